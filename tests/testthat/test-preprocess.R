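test_that("quantile normalization matches the hand oracle and its defining property", {
  m <- cbind(a = c(5, 3, 1), b = c(2, 4, 6))
  qn <- quantile_normalize(m)
  # sorted-column means are (1.5, 3.5, 5.5)
  expect_equal(unname(qn[, "a"]), c(5.5, 3.5, 1.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5, 5.5))
  # identical columns come back unchanged
  m2 <- cbind(x = c(1, 2, 7), y = c(1, 2, 7))
  expect_equal(quantile_normalize(m2), m2)
  # defining property: all columns share one sorted multiset
  set.seed(1)
  r <- matrix(stats::rexp(200) + 0.01, ncol = 4)
  qr <- quantile_normalize(r)
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # rank order preserved within columns
  expect_equal(apply(qr, 2, rank), apply(r, 2, rank))
})

test_that("quantile normalization is idempotent and validates input", {
  set.seed(2)
  r <- matrix(stats::runif(150, 1, 100), ncol = 3)
  once <- quantile_normalize(r)
  expect_equal(quantile_normalize(once), once)
  expect_error(quantile_normalize(-r), "positive")
  expect_warning(qn1 <- quantile_normalize(r[, 1, drop = FALSE]),
                 "single-sample")
  expect_equal(qn1, r[, 1, drop = FALSE])
})

test_that("median polish satisfies reconstruction and residual-median-zero", {
  set.seed(3)
  for (dims in list(c(5, 7), c(2, 9), c(12, 3))) {
    x <- matrix(stats::rnorm(prod(dims)), nrow = dims[1])
    fit <- median_polish(x, max_iter = 50L, tol = 1e-10)
    recon <- fit$overall + outer(fit$row, fit$col, "+") + fit$residuals
    expect_lt(max(abs(recon - x)), 1e-9)
    expect_lt(max(abs(apply(fit$residuals, 1, stats::median))), 1e-6)
    expect_lt(max(abs(apply(fit$residuals, 2, stats::median))), 1e-6)
  }
})

test_that("median polish agrees with the reference rows-first sweeps", {
  # hand-iterated oracle for [[0,0],[0,4]]: row medians (0,2), then column
  # medians (-1,1) leave residuals [[1,-1],[-1,1]]; further sweeps change
  # nothing
  fit <- median_polish(matrix(c(0, 0, 0, 4), nrow = 2, byrow = TRUE))
  expect_equal(unname(fit$residuals), matrix(c(1, -1, -1, 1), 2,
                                             byrow = TRUE))
  # independent implementation: stats::medpolish (also rows first; it
  # stops on a sum-of-absolute-residuals criterion that can trigger while
  # cells still move, so agreement is to polish accuracy, not machine
  # precision)
  set.seed(4)
  for (i in 1:5) {
    # odd dimensions: medians are data points and both implementations
    # reach the same fixed point exactly; with even dimensions the
    # reference's sum-abs stopping rule halts before the fixed point
    x <- matrix(stats::rnorm(35), nrow = 5)
    ours <- median_polish(x, max_iter = 200L, tol = 1e-12)
    ref <- stats::medpolish(x, eps = 1e-12, maxiter = 200L,
                            trace.iter = FALSE)
    expect_equal(ours$residuals, ref$residuals, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ours$overall, ref$overall, tolerance = 1e-10)
    # even-dimension fits still land on a genuine fixed point of the sweeps
    xe <- matrix(stats::rnorm(48), nrow = 6)
    fe <- median_polish(xe, max_iter = 200L, tol = 1e-12)
    again <- median_polish(fe$residuals, max_iter = 1L, tol = 0)
    expect_lt(max(abs(again$residuals - fe$residuals)), 1e-9)
  }
})

test_that("median polish handles additive and degenerate shapes", {
  # exactly additive input leaves zero residuals
  x <- outer(c(1, 3), c(0, 1)) * 0 + outer(c(1, 3), c(0, 1), "+")
  fit <- median_polish(x)
  expect_equal(max(abs(fit$residuals)), 0)
  expect_true(fit$converged)
  # 1 x n input: single chip effect absorbs the row, residuals vanish
  fit1 <- median_polish(matrix(c(2, 5, 9), nrow = 1))
  expect_equal(max(abs(fit1$residuals)), 0)
  expect_error(median_polish(matrix(numeric(0), 0, 0)), "empty")
})

test_that("median polish is equivariant under row/column permutation", {
  set.seed(5)
  x <- matrix(stats::rnorm(40), nrow = 5)
  pr <- sample(5)
  pc <- sample(8)
  f1 <- median_polish(x, max_iter = 50L, tol = 1e-12)
  f2 <- median_polish(x[pr, pc], max_iter = 50L, tol = 1e-12)
  expect_equal(f2$residuals, f1$residuals[pr, pc], tolerance = 1e-9)
})

test_that("gene models are fitted independently per cluster", {
  d <- generate_dataset(sim_config(n_samples = 6L, n_genes = 2L,
                                   exons_per_gene = 3L,
                                   probes_per_exon = 2L, n_sf_genes = 1L,
                                   coupling_beta = 0,
                                   baseline_events_n0 = 1, seed = 9L))
  fits <- fit_gene_models(d$intensities, d$annotation)
  lvals <- log2(d$intensities)
  for (g in names(fits)) {
    idx <- d$annotation$transcript_cluster_id == g
    solo <- median_polish(t(lvals[idx, , drop = FALSE]))
    expect_equal(fits[[g]]$residuals, solo$residuals, tolerance = 1e-12)
  }
  # reconstruction identity on every fitted cluster
  for (g in names(fits)) {
    f <- fits[[g]]
    idx <- match(f$probe_ids, rownames(lvals))
    recon <- f$overall + outer(f$row, f$col, "+") + f$residuals
    expect_lt(max(abs(recon - t(lvals[idx, , drop = FALSE]))), 1e-9)
  }
  expect_error(fit_gene_models(d$intensities, d$annotation[-1, ]),
               "without annotation")
})

test_that("a planted shift surfaces in that exon's residuals", {
  d <- generate_dataset(sim_config(n_samples = 10L, n_genes = 8L,
                                   exons_per_gene = 8L,
                                   probes_per_exon = 4L, n_sf_genes = 2L,
                                   baseline_events_n0 = 2,
                                   coupling_beta = 0,
                                   event_magnitude_delta = 3,
                                   noise_sd = 0.1, seed = 12L))
  ev <- d$truth$planted_events[1, ]
  fits <- fit_gene_models(d$intensities, d$annotation)
  f <- fits[[ev$gene]]
  in_ps <- f$probeset_ids == ev$probeset_id
  res <- f$residuals[ev$sample_id, ]
  expect_true(all(abs(res[in_ps] - ev$sign * 3) < 0.3))
  # exons of the same gene without an event stay near zero
  other_ev <- d$truth$planted_events
  hit <- other_ev$probeset_id[other_ev$sample_id == ev$sample_id &
                                other_ev$gene == ev$gene]
  quiet <- !f$probeset_ids %in% hit
  expect_true(all(abs(res[quiet]) < 0.3))
})

test_that("all-constant input yields zero chip effects and residuals", {
  ann <- data.frame(probe_id = paste0("p", 1:6),
                    probeset_id = rep(c("ps1", "ps2"), each = 3),
                    transcript_cluster_id = "g1")
  m <- matrix(8, nrow = 6, ncol = 4,
              dimnames = list(ann$probe_id, paste0("s", 1:4)))
  fits <- fit_gene_models(m, ann)
  expect_equal(max(abs(fits$g1$residuals)), 0)
  expect_equal(max(abs(fits$g1$row)), 0)
})

test_that("gene-level expression recovers planted chip effects up to a constant", {
  cfg <- sim_config(n_samples = 12L, n_genes = 10L, exons_per_gene = 4L,
                    probes_per_exon = 3L, n_sf_genes = 3L,
                    baseline_events_n0 = 1, coupling_beta = 0,
                    event_magnitude_delta = 0, noise_sd = 0, seed = 21L)
  d <- generate_dataset(cfg)
  fits <- fit_gene_models(d$intensities, d$annotation)
  expr <- gene_level_expression(fits)
  expect_equal(dim(expr), c(10L, 12L))
  # reconstruct the true a_gi from the noise-free log2 data: it is the
  # probe-median per gene/sample minus the probe effect, i.e. expression
  # must match the per-gene centered truth
  lv <- log2(d$intensities)
  for (g in rownames(expr)[1:4]) {
    idx <- d$annotation$transcript_cluster_id == g
    truth <- colMeans(lv[idx, , drop = FALSE])   # a_gi + mean(b_p)
    expect_lt(max(abs((expr[g, ] - mean(expr[g, ])) -
                        (truth - mean(truth)))), 1e-8)
  }
  # constant matrix gives constant expression
  ann <- data.frame(probe_id = paste0("p", 1:4),
                    probeset_id = c("a", "a", "b", "b"),
                    transcript_cluster_id = "g1")
  m <- matrix(4, 4, 3, dimnames = list(ann$probe_id, paste0("s", 1:3)))
  e2 <- gene_level_expression(fit_gene_models(m, ann))
  expect_equal(unname(diff(range(e2))), 0)
})
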