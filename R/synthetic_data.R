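#' Configuration for the synthetic exon-array generator
#'
#' Bundles all knobs of the generative model used by [generate_dataset()].
#' The model emulates the post-CEL structure of an Affymetrix exon array:
#' multi-probe probesets (exons) nested in transcript clusters (genes),
#' log-normal intensity noise, additive gene models, and per-sample aberrant
#' exon-level shifts whose counts are negatively coupled to a latent
#' splicing-capacity variable that also drives splicing-factor expression.
#'
#' The latent variable `z_i ~ N(0, 1)` enters twice: splicing-factor genes
#' load on it with `sf_loading_lambda` (their log2 chip effect is
#' `mu_g + lambda * z_i`), and the number of planted aberrant exon events in
#' sample `i` is `N_i = max(0, round(baseline_events_n0 * 2^(-coupling_beta *
#' z_i)))`. With `coupling_beta > 0` a sample with low splicing-factor
#' expression (low `z`) therefore carries more aberrant events — the inverse
#' relationship the pipeline is designed to detect. `coupling_beta = 0` gives
#' a null model with no coupling.
#'
#' @param n_samples number of samples (arrays).
#' @param n_genes number of transcript clusters.
#' @param exons_per_gene probesets per transcript cluster.
#' @param probes_per_exon probes per probeset (exon arrays average four).
#' @param n_sf_genes size of the splicing-factor subset (first genes).
#' @param coupling_beta log2 events per unit latent z, >= 0; 0 = null model.
#' @param baseline_events_n0 mean planted aberrant exon events per sample.
#' @param event_magnitude_delta log2 shift applied to all probes of an
#'   aberrant exon.
#' @param event_inclusion_fraction probability that a planted event is an
#'   inclusion (positive shift) rather than a skipping (negative shift).
#' @param sf_loading_lambda loading of splicing-factor genes on z, >= 0.
#' @param noise_sd per-probe log2 noise standard deviation.
#' @param gene_mu_range interval for uniform baseline gene means (log2).
#' @param group_labels optional per-sample categorical labels (length
#'   `n_samples`); `group_effect` log2 units are added to the event-count
#'   exponent of samples in the second level.
#' @param group_effect log2 modifier of event counts for the second group.
#' @param paired if `TRUE`, samples are generated in matched pairs and a
#'   `pair_id` column is emitted in the metadata (`n_samples` must be even).
#' @param count_model `"deterministic"` (rounded log-linear function of z)
#'   or `"poisson"` (Poisson draws with the same mean).
#' @param seed integer seed; the whole dataset is reproducible from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 60L, n_genes = 300L, exons_per_gene = 8L,
                       probes_per_exon = 4L, n_sf_genes = 40L,
                       coupling_beta = 1, baseline_events_n0 = 40,
                       event_magnitude_delta = 3,
                       event_inclusion_fraction = 0.5,
                       sf_loading_lambda = 1, noise_sd = 0.25,
                       gene_mu_range = c(6, 12),
                       group_labels = NULL, group_effect = 0,
                       paired = FALSE,
                       count_model = c("deterministic", "poisson"),
                       seed = 1L) {
  count_model <- match.arg(count_model)
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    probes_per_exon = as.integer(probes_per_exon),
    n_sf_genes = as.integer(n_sf_genes),
    coupling_beta = coupling_beta,
    baseline_events_n0 = baseline_events_n0,
    event_magnitude_delta = event_magnitude_delta,
    event_inclusion_fraction = event_inclusion_fraction,
    sf_loading_lambda = sf_loading_lambda,
    noise_sd = noise_sd, gene_mu_range = gene_mu_range,
    group_labels = group_labels, group_effect = group_effect,
    paired = isTRUE(paired), count_model = count_model,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_samples, cfg$n_genes, cfg$exons_per_gene,
              cfg$probes_per_exon, cfg$n_sf_genes)
  if (any(counts < 1L)) stop("all count parameters must be >= 1")
  if (cfg$n_sf_genes > cfg$n_genes)
    stop("n_sf_genes must not exceed n_genes")
  if (cfg$event_inclusion_fraction < 0 || cfg$event_inclusion_fraction > 1)
    stop("event_inclusion_fraction must lie in [0, 1]")
  if (cfg$coupling_beta < 0 || cfg$sf_loading_lambda < 0)
    stop("coupling_beta and sf_loading_lambda must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$gene_mu_range) != 2L ||
      cfg$gene_mu_range[1] > cfg$gene_mu_range[2])
    stop("gene_mu_range must be an increasing interval")
  if (!is.null(cfg$group_labels)) {
    if (length(cfg$group_labels) != cfg$n_samples)
      stop("group_labels must have length n_samples")
    if (length(unique(cfg$group_labels)) != 2L)
      stop("group_labels must define exactly two groups")
  }
  if (cfg$paired && cfg$n_samples %% 2L != 0L)
    stop("paired design requires an even n_samples")
  total_exons <- cfg$n_genes * cfg$exons_per_gene
  # a sample 3 sd below the latent mean must still be drawable w/o replacement
  if (cfg$baseline_events_n0 * 2^(cfg$coupling_beta * 3) > total_exons)
    stop("baseline_events_n0 * 2^(3*coupling_beta) exceeds the total exon ",
         "count (", total_exons, "); events cannot be drawn without ",
         "replacement")
  structure(cfg, class = "sim_config")
}

#' Stable synthetic gene identifiers
#'
#' Returns `n_genes` unique, zero-padded gene identifiers. Generation is
#' order-stable and does not consume randomness, so the result is identical
#' for any seed; the `seed` argument is accepted for interface symmetry with
#' the other generators.
#'
#' @param n_genes number of identifiers, >= 1.
#' @param seed ignored (generation is deterministic).
#' @return character vector of `n_genes` unique identifiers.
#' @export
make_random_gene_universe <- function(n_genes, seed = NULL) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  width <- max(5L, nchar(as.character(n_genes)))
  sprintf("gene%0*d", width, seq_len(n_genes))
}

#' Generate a synthetic exon-array dataset with planted aberrant splicing
#'
#' Draws a complete probe-level dataset from the generative model described
#' in [sim_config()], together with its annotation, splicing-factor gene
#' set, sample metadata and the ground truth of planted events.
#'
#' Per sample `i`: latent `z_i ~ N(0,1)`; gene-level chip effect
#' `a_gi = mu_g + N(0, 0.5) + lambda * z_i` for splicing-factor genes and
#' `mu_g + N(0, 0.5)` otherwise (all genes share the same idiosyncratic
#' variation; splicing factors additionally load on the latent splicing
#' capacity); fixed probe effects `b_p ~ N(0, 0.5)`;
#' log2 intensity `a_gi + b_p + N(0, noise_sd)`. `N_i` distinct exons are
#' drawn uniformly without replacement and all probes of each chosen exon
#' are shifted by `+delta` (inclusion) or `-delta` (skipping). Returned
#' intensities are `2^log2value`, strictly positive and linear scale.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#' \describe{
#'   \item{intensities}{numeric matrix probes x samples, linear scale,
#'     dimnames = probe ids / sample ids.}
#'   \item{annotation}{data.frame with columns `probe_id`, `probeset_id`,
#'     `transcript_cluster_id`.}
#'   \item{genesets}{list of gene sets (each `list(name, description,
#'     genes)`); the first is the splicing-factor set.}
#'   \item{metadata}{data.frame with `sample_id` and optional `group`,
#'     `pair_id` columns.}
#'   \item{truth}{list with `z`, `planted_events` (data.frame sample_id,
#'     gene, exon, probeset_id, sign, magnitude), `planted_counts`,
#'     `sf_gene_ids` and `config` (the echoed configuration).}
#' }
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  e <- config$exons_per_gene
  p <- config$probes_per_exon
  total_exons <- g * e
  total_probes <- total_exons * p

  gene_ids <- make_random_gene_universe(g)
  sf_ids <- gene_ids[seq_len(config$n_sf_genes)]
  probeset_ids <- paste0(rep(gene_ids, each = e), "_e",
                         sprintf("%02d", rep(seq_len(e), times = g)))
  probe_ids <- paste0(rep(probeset_ids, each = p), "_p",
                      rep(seq_len(p), times = total_exons))
  sample_ids <- sprintf("s%03d", seq_len(n))

  annotation <- data.frame(
    probe_id = probe_ids,
    probeset_id = rep(probeset_ids, each = p),
    transcript_cluster_id = rep(gene_ids, each = e * p),
    stringsAsFactors = FALSE
  )

  z <- stats::rnorm(n)
  mu <- stats::runif(g, config$gene_mu_range[1], config$gene_mu_range[2])
  is_sf <- gene_ids %in% sf_ids

  # gene x sample log2 chip effects: every gene has idiosyncratic
  # variation (sd 0.5); splicing-factor genes additionally load on z
  a <- matrix(mu, nrow = g, ncol = n) +
    matrix(stats::rnorm(g * n, sd = 0.5), nrow = g)
  a[is_sf, ] <- a[is_sf, , drop = FALSE] +
    config$sf_loading_lambda * matrix(z, nrow = sum(is_sf), ncol = n,
                                      byrow = TRUE)

  b <- stats::rnorm(total_probes, sd = 0.5)
  gene_of_probe <- rep(seq_len(g), each = e * p)
  m <- a[gene_of_probe, , drop = FALSE] + b +
    matrix(stats::rnorm(total_probes * n, sd = config$noise_sd),
           nrow = total_probes)

  # planted event counts coupled to z (log2-linear), optional group modifier
  eta <- -config$coupling_beta * z
  group <- config$group_labels
  if (!is.null(group)) {
    lev <- unique(group)
    eta <- eta + config$group_effect * as.numeric(group == lev[2])
  }
  lambda_i <- config$baseline_events_n0 * 2^eta
  n_events <- if (config$count_model == "poisson") {
    stats::rpois(n, lambda_i)
  } else {
    pmax(0, round(lambda_i))
  }
  if (any(n_events > total_exons))
    stop("planted event count exceeds the number of exons for sample ",
         sample_ids[which.max(n_events)])

  events <- vector("list", n)
  exon_of_probe <- rep(seq_len(total_exons), each = p)
  for (i in seq_len(n)) {
    k <- n_events[i]
    if (k == 0L) next
    exons <- sample.int(total_exons, k)
    signs <- ifelse(stats::runif(k) < config$event_inclusion_fraction, 1, -1)
    rows <- which(exon_of_probe %in% exons)
    shift <- signs[match(exon_of_probe[rows], exons)] *
      config$event_magnitude_delta
    m[rows, i] <- m[rows, i] + shift
    events[[i]] <- data.frame(
      sample_id = sample_ids[i],
      gene = gene_ids[(exons - 1L) %/% e + 1L],
      exon = (exons - 1L) %% e + 1L,
      probeset_id = probeset_ids[exons],
      sign = signs,
      magnitude = config$event_magnitude_delta,
      stringsAsFactors = FALSE
    )
  }
  planted_events <- do.call(rbind, events)
  if (is.null(planted_events))
    planted_events <- data.frame(sample_id = character(), gene = character(),
                                 exon = integer(), probeset_id = character(),
                                 sign = numeric(), magnitude = numeric())

  intensities <- 2^m
  dimnames(intensities) <- list(probe_ids, sample_ids)

  metadata <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(group)) metadata$group <- group
  if (config$paired) metadata$pair_id <- rep(sprintf("pair%03d",
                                                     seq_len(n / 2L)),
                                             each = 2L)

  genesets <- list(list(
    name = "SPLICING_FACTORS",
    description = "synthetic splicing-factor gene set (loads on latent z)",
    genes = sf_ids
  ))

  list(
    intensities = intensities,
    annotation = annotation,
    genesets = genesets,
    metadata = metadata,
    truth = list(z = stats::setNames(z, sample_ids),
                 planted_events = planted_events,
                 planted_counts = stats::setNames(as.integer(n_events),
                                                  sample_ids),
                 sf_gene_ids = sf_ids,
                 config = config)
  )
}
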