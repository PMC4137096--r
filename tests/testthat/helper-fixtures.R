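# Shared fixtures and oracles. Heavy fixtures are generated once per run
# and cached; everything is rebuilt from code, nothing is stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

# Run the deterministic pipeline stages (no resampling, no multivariate).
run_core <- function(d, qn = TRUE) {
  x <- if (qn) quantile_normalize(d$intensities) else d$intensities
  fits <- fit_gene_models(x, d$annotation)
  scores <- firma_scores(fits)
  thr <- suppressWarnings(compute_thresholds(scores))
  counts <- count_aberrant_exons(scores, thr)
  tin <- suppressMessages(compute_tin_estimates(counts))
  expr <- gene_level_expression(fits)
  list(fits = fits, scores = scores, thresholds = thr, counts = counts,
       tin = tin, expr = expr)
}

# The strong-coupling study fixture: 60 samples x 300 genes (40 splicing
# factors), beta = 1, delta = 3, noise_sd = 0.25 — the package defaults.
strong_fixture <- function() {
  if (!exists("strong", .fixture_cache)) {
    d <- generate_dataset(sim_config(seed = 1L))
    assign("strong", c(list(data = d), run_core(d)), .fixture_cache)
  }
  get("strong", .fixture_cache)
}

# Scaled-down strong-coupling configuration for replicate-based checks.
small_strong_cfg <- function(seed = 1L, n_samples = 24L, n_genes = 80L,
                             exons_per_gene = 6L, probes_per_exon = 3L,
                             n_sf_genes = 16L, coupling_beta = 1,
                             baseline_events_n0 = 8,
                             event_magnitude_delta = 3, noise_sd = 0.25,
                             ...) {
  sim_config(n_samples = n_samples, n_genes = n_genes,
             exons_per_gene = exons_per_gene,
             probes_per_exon = probes_per_exon, n_sf_genes = n_sf_genes,
             coupling_beta = coupling_beta,
             baseline_events_n0 = baseline_events_n0,
             event_magnitude_delta = event_magnitude_delta,
             noise_sd = noise_sd, seed = seed, ...)
}

# Complete null: no coupling and no splicing-factor loading.
null_cfg <- function(seed = 1L, coupling_beta = 0, sf_loading_lambda = 0,
                     ...) {
  small_strong_cfg(seed = seed, n_samples = 20L, n_genes = 40L,
                   exons_per_gene = 5L, probes_per_exon = 3L,
                   n_sf_genes = 10L, coupling_beta = coupling_beta,
                   sf_loading_lambda = sf_loading_lambda,
                   baseline_events_n0 = 10, ...)
}

# Noise-free sparse fixture: planted events are the only signal and the
# planted fraction per side stays below the 1st-percentile rule, so FIRMA
# residuals are exactly 0 / +-delta and counts recover the truth exactly.
noisefree_cfg <- function(seed = 1L, event_magnitude_delta = 3, ...) {
  small_strong_cfg(seed = seed, n_samples = 20L, n_genes = 60L,
                   exons_per_gene = 8L, probes_per_exon = 4L,
                   n_sf_genes = 10L, coupling_beta = 0.5,
                   baseline_events_n0 = 3,
                   event_magnitude_delta = event_magnitude_delta,
                   noise_sd = 0, ...)
}

# Two-sided permutation p-value for a Pearson correlation (independent
# small-instance oracle for the analytic Student p).
perm_p_oracle <- function(x, y, n_perm = 10000L, seed = 1L) {
  r_obs <- abs(cor(x, y))
  set.seed(seed)
  hits <- sum(vapply(seq_len(n_perm),
                     function(b) abs(cor(x, y[sample.int(length(y))])),
                     numeric(1)) >= r_obs - 1e-12)
  (hits + 1) / (n_perm + 1)
}

# Manual thresholds object for unit tests.
thresholds_at <- function(lower, upper) {
  structure(list(lower = lower, upper = upper,
                 lower_percentile = 1, upper_percentile = 99),
            class = "aberrance_thresholds")
}
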