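test_that("generated dataset has the configured array structure", {
  cfg <- sim_config(n_genes = 50L, exons_per_gene = 8L,
                    probes_per_exon = 4L, n_samples = 10L,
                    n_sf_genes = 10L, baseline_events_n0 = 10)
  d <- generate_dataset(cfg)
  expect_equal(dim(d$intensities), c(50L * 8L * 4L, 10L))
  expect_true(all(d$intensities > 0))
  expect_false(anyDuplicated(rownames(d$intensities)) > 0)
  expect_equal(d$annotation$probe_id, rownames(d$intensities))
  # each probeset maps to one cluster, each cluster has the right exon count
  per_ps <- tapply(d$annotation$transcript_cluster_id,
                   d$annotation$probeset_id,
                   function(x) length(unique(x)))
  expect_true(all(per_ps == 1L))
  per_gene <- tapply(d$annotation$probeset_id,
                     d$annotation$transcript_cluster_id,
                     function(x) length(unique(x)))
  expect_true(all(per_gene == 8L))
})

test_that("generation is bit-identical given the same seed", {
  d1 <- generate_dataset(sim_config(n_samples = 8L, n_genes = 20L,
                                    exons_per_gene = 4L,
                                    probes_per_exon = 3L, n_sf_genes = 5L,
                                    baseline_events_n0 = 5, seed = 42L))
  d2 <- generate_dataset(sim_config(n_samples = 8L, n_genes = 20L,
                                    exons_per_gene = 4L,
                                    probes_per_exon = 3L, n_sf_genes = 5L,
                                    baseline_events_n0 = 5, seed = 42L))
  expect_identical(d1$intensities, d2$intensities)
  expect_identical(d1$truth$planted_events, d2$truth$planted_events)
  d3 <- generate_dataset(sim_config(n_samples = 8L, n_genes = 20L,
                                    exons_per_gene = 4L,
                                    probes_per_exon = 3L, n_sf_genes = 5L,
                                    baseline_events_n0 = 5, seed = 43L))
  expect_false(identical(d1$intensities, d3$intensities))
})

test_that("planted-event bookkeeping is exact", {
  d <- generate_dataset(small_strong_cfg(seed = 3L))
  ev <- d$truth$planted_events
  counted <- table(factor(ev$sample_id,
                          levels = names(d$truth$planted_counts)))
  expect_equal(as.integer(counted), as.integer(d$truth$planted_counts))
  # every event references a valid (gene, exon) pair and its probeset
  cfg <- d$truth$config
  expect_true(all(ev$exon >= 1 & ev$exon <= cfg$exons_per_gene))
  expect_true(all(ev$probeset_id %in% d$annotation$probeset_id))
  expect_true(all(ev$gene %in% unique(d$annotation$transcript_cluster_id)))
  # no (sample, exon) drawn twice
  expect_false(anyDuplicated(ev[, c("sample_id", "probeset_id")]) > 0)
})

test_that("planted shifts touch exactly the recorded probe cells", {
  cfg <- noisefree_cfg(seed = 11L)
  d <- generate_dataset(cfg)
  # rebuild the unshifted log2 matrix from an identical generation with
  # delta = 0: the set of differing cells is exactly the planted cells
  cfg0 <- noisefree_cfg(seed = 11L, event_magnitude_delta = 0)
  d0 <- generate_dataset(cfg0)
  diff <- log2(d$intensities) - log2(d0$intensities)
  ev <- d$truth$planted_events
  shifted <- abs(diff) > 1e-9
  expect_equal(sum(shifted),
               nrow(ev) * cfg$probes_per_exon)
  for (i in sample(nrow(ev), min(10, nrow(ev)))) {
    pr <- d$annotation$probe_id[d$annotation$probeset_id ==
                                  ev$probeset_id[i]]
    expect_equal(unname(diff[pr, ev$sample_id[i]]),
                 rep(ev$sign[i] * 3, length(pr)))
  }
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(n_sf_genes = 10L, n_genes = 5L), "n_sf_genes")
  expect_error(sim_config(event_inclusion_fraction = 1.5), "inclusion")
  expect_error(sim_config(n_samples = 0L), "count")
  # event budget: cannot draw without replacement 3 sd below the mean
  expect_error(sim_config(n_genes = 10L, exons_per_gene = 4L,
                          n_sf_genes = 2L,
                          baseline_events_n0 = 30, coupling_beta = 1),
               "without replacement")
})

test_that("group effect raises event counts in the labelled group", {
  labels <- rep(c("a", "b"), each = 12L)
  d <- generate_dataset(small_strong_cfg(
    seed = 5L, coupling_beta = 0, group_labels = labels, group_effect = 2))
  counts <- d$truth$planted_counts
  expect_gt(mean(counts[labels == "b"]), 3 * mean(counts[labels == "a"]))
  expect_identical(d$metadata$group, labels)
})

test_that("paired designs emit pair ids and poisson counts vary", {
  d <- generate_dataset(small_strong_cfg(seed = 6L, paired = TRUE))
  expect_true("pair_id" %in% names(d$metadata))
  expect_true(all(table(d$metadata$pair_id) == 2L))
  dp <- generate_dataset(small_strong_cfg(seed = 6L, coupling_beta = 0,
                                          count_model = "poisson"))
  # deterministic model would give constant counts at beta = 0
  expect_gt(stats::var(dp$truth$planted_counts), 0)
})

test_that("gene universe identifiers are unique, stable and seed-free", {
  u <- make_random_gene_universe(3)
  expect_length(unique(u), 3L)
  expect_identical(make_random_gene_universe(100, seed = 1),
                   make_random_gene_universe(100, seed = 999))
  big <- make_random_gene_universe(17881)
  expect_length(unique(big), 17881L)
  expect_error(make_random_gene_universe(0), ">= 1")
})

test_that("planted association has a negative sign in expectation", {
  mean_r <- vapply(1:20, function(s) {
    d <- generate_dataset(small_strong_cfg(seed = 100L + s))
    core <- run_core(d)
    rec <- correlate_genes_with_tin(core$expr, core$tin,
                                    d$truth$sf_gene_ids)
    mean(rec$r[!rec$degenerate])
  }, numeric(1))
  expect_true(all(mean_r < 0))
  expect_lt(mean(mean_r), -0.5)
})

test_that("analytic correlation test keeps its size on null data", {
  # complete null (no coupling, no loading): the fraction of splicing-
  # factor genes reaching p < 0.05 should average the nominal 5%
  frac <- vapply(1:100, function(s) {
    d <- generate_dataset(null_cfg(seed = 2000L + s))
    core <- run_core(d)
    rec <- correlate_genes_with_tin(core$expr, core$tin,
                                    d$truth$sf_gene_ids)
    mean(rec$p[!rec$degenerate] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})
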