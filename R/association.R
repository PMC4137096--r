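# Vectorized Pearson correlation of each gene (row of x) with y, with the
# two-sided Student p from t = r * sqrt((n-2) / (1-r^2)) on n-2 df.
# Zero-variance genes get r = 0, p = NA, degenerate = TRUE.
cor_with_p <- function(x, y) {
  n <- length(y)
  sx <- apply(x, 1L, stats::sd)
  degenerate <- sx == 0 | stats::sd(y) == 0
  r <- rep(0, nrow(x))
  ok <- !degenerate
  if (any(ok)) r[ok] <- as.numeric(stats::cor(t(x[ok, , drop = FALSE]), y))
  r <- pmin(1, pmax(-1, r))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  p[degenerate] <- NA_real_
  list(r = r, p = p, n = n, degenerate = degenerate)
}

#' Correlate gene expression with TIN-estimates
#'
#' One Pearson correlation per gene-set member present in the expression
#' matrix, against the sample-wise TIN-estimates, with two-sided Student
#' p-values. Genes in the set but absent from the expression matrix are
#' reported in the `skipped` attribute, never silently dropped.
#'
#' @param expr gene expression matrix (genes x samples, log2), sample ids
#'   as colnames.
#' @param tin a `tin_profile` whose `sample_id`s match `colnames(expr)`
#'   exactly and in order.
#' @param gene_set character vector of gene ids to test; default all genes.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of class `tin_correlations` with columns `gene_id`,
#'   `r`, `p`, `n`, `significant`, `degenerate`; attribute `skipped` lists
#'   absent genes. Degenerate (zero-variance) genes carry `r = 0`, `p = NA`
#'   and are excluded from summaries.
#' @export
correlate_genes_with_tin <- function(expr, tin, gene_set = rownames(expr),
                                     alpha = 0.05) {
  if (!identical(colnames(expr), tin$sample_id))
    stop("expression matrix and TIN profile must share identical, aligned ",
         "sample ids")
  n <- ncol(expr)
  if (n < 3L) stop("correlation requires at least 3 samples")
  present <- intersect(gene_set, rownames(expr))
  skipped <- setdiff(gene_set, rownames(expr))
  if (length(present) == 0L) stop("no gene-set member present in expr")
  cp <- cor_with_p(expr[present, , drop = FALSE], tin$tin_estimate)
  out <- data.frame(
    gene_id = present, r = cp$r, p = cp$p, n = n,
    significant = !is.na(cp$p) & cp$p < alpha,
    degenerate = cp$degenerate,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("tin_correlations", "data.frame"),
            skipped = skipped, alpha = alpha)
}

#' Summarize a table of gene-TIN correlations
#'
#' Counts significantly correlated genes at `p < alpha`, their sign split
#' and the negative:positive ratio, the mean correlation among significant
#' genes, and the mean absolute correlation over all non-degenerate genes
#' (the correlation-strength statistic).
#'
#' @param records a `tin_correlations` data.frame (or compatible) with
#'   columns `gene_id`, `r`, `p`, `degenerate`.
#' @param alpha significance level.
#' @param set_name label carried into the summary row.
#' @return one-row data.frame of class `association_summary` with columns
#'   `set_name`, `n_genes_tested`, `pct_significant`, `mean_r_significant`,
#'   `n_neg_significant`, `n_pos_significant`, `neg_pos_ratio` (`Inf` when
#'   no positive, `NA` when no significant genes), `mean_abs_r`, `alpha`.
#' @export
summarize_association <- function(records, alpha = 0.05, set_name = "set") {
  ok <- !records$degenerate & !is.na(records$p)
  if (!any(ok)) stop("all correlation records are degenerate")
  rec <- records[ok, , drop = FALSE]
  sig <- rec$p < alpha
  n_neg <- sum(sig & rec$r < 0)
  n_pos <- sum(sig & rec$r > 0)
  ratio <- if (n_neg + n_pos == 0L) NA_real_ else n_neg / n_pos
  out <- data.frame(
    set_name = set_name,
    n_genes_tested = nrow(rec),
    pct_significant = 100 * mean(sig),
    mean_r_significant = if (any(sig)) mean(rec$r[sig]) else NA_real_,
    n_neg_significant = n_neg,
    n_pos_significant = n_pos,
    neg_pos_ratio = ratio,
    mean_abs_r = mean(abs(rec$r)),
    alpha = alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("association_summary", "data.frame")
  out
}

#' Two-group comparison of TIN-estimates (pooled-variance t-test)
#'
#' Classic independent-samples Student t-test (pooled variance, two-sided)
#' of the TIN-estimates between two groups of samples.
#'
#' @param tin a `tin_profile`.
#' @param labels factor/character vector aligned with `tin$sample_id`,
#'   exactly two levels, each with >= 2 samples.
#' @return list with `t`, `p`, `df`, `group_means`.
#' @export
independent_ttest <- function(tin, labels) {
  labels <- as.factor(labels)
  if (length(labels) != nrow(tin))
    stop("labels must align with the TIN profile samples")
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  x <- split(tin$tin_estimate, labels)
  n1 <- length(x[[1]]); n2 <- length(x[[2]])
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  m1 <- mean(x[[1]]); m2 <- mean(x[[2]])
  sp2 <- ((n1 - 1) * stats::var(x[[1]]) + (n2 - 1) * stats::var(x[[2]])) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = n1 + n2 - 2,
                              group_means = c(m1, m2)))
    stop("degenerate separation: zero pooled variance with unequal means")
  }
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval,
       p = 2 * stats::pt(abs(tval), df = n1 + n2 - 2, lower.tail = FALSE),
       df = n1 + n2 - 2,
       group_means = c(m1, m2))
}

#' Correlation of TIN-estimates between paired cohorts
#'
#' Pearson correlation of TIN-estimates across matched sample pairs from
#' two cohorts scored as separate datasets (e.g. tumors and their paired
#' normals). Pairs with a member missing from either profile are skipped
#' and reported.
#'
#' @param tin_a,tin_b `tin_profile`s of the two cohorts.
#' @param pairing data.frame with columns `sample_a`, `sample_b` mapping
#'   samples of `tin_a` to samples of `tin_b`.
#' @return list with `r`, `p`, `n` (complete pairs) and `skipped` (rows of
#'   `pairing` that could not be matched).
#' @export
paired_tin_correlation <- function(tin_a, tin_b, pairing) {
  ia <- match(pairing$sample_a, tin_a$sample_id)
  ib <- match(pairing$sample_b, tin_b$sample_id)
  complete <- !is.na(ia) & !is.na(ib)
  skipped <- pairing[!complete, , drop = FALSE]
  if (nrow(skipped) > 0L)
    warning(nrow(skipped), " pair(s) skipped: sample(s) missing from a ",
            "TIN profile")
  if (sum(complete) < 3L) stop("fewer than 3 complete pairs")
  a <- tin_a$tin_estimate[ia[complete]]
  b <- tin_b$tin_estimate[ib[complete]]
  cp <- cor_with_p(matrix(a, nrow = 1L), b)
  list(r = cp$r, p = cp$p, n = sum(complete), skipped = skipped)
}
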