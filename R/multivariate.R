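#' Covariance PCA of samples in gene-expression space
#'
#' Principal components analysis by singular value decomposition of the
#' covariance matrix: samples are the observations, genes the variables;
#' variables are centered but not scaled. Component signs are fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param expr gene expression matrix (genes x samples, log2).
#' @return list of class `pca_result` with `scores` (samples x components),
#'   `loadings` (genes x components), `variance_fraction` (per component,
#'   non-increasing, summing to 1).
#' @export
pca_covariance <- function(expr) {
  if (ncol(expr) < 2L || nrow(expr) < 1L)
    stop("PCA needs >= 2 samples and >= 1 gene")
  obs <- t(expr)    # samples x genes
  if (sum(apply(obs, 2L, stats::var)) == 0)
    stop("zero total variance: PCA undefined")
  fit <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    i <- which.max(abs(fit$rotation[, j]))
    fit$rotation[i, j] < 0
  }, logical(1))
  fit$rotation[, flip] <- -fit$rotation[, flip, drop = FALSE]
  fit$x[, flip] <- -fit$x[, flip, drop = FALSE]
  structure(list(scores = fit$x,
                 loadings = fit$rotation,
                 variance_fraction = fit$sdev^2 / sum(fit$sdev^2)),
            class = "pca_result")
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on Euclidean distances over the
#' given genes, with complete linkage (merge heights are therefore
#' non-decreasing). Returns the standard `hclust` object (merge table,
#' heights, leaf order).
#'
#' @param expr gene expression matrix (genes x samples).
#' @return an object of class `hclust`.
#' @export
hierarchical_clustering <- function(expr) {
  if (ncol(expr) < 2L) stop("clustering needs >= 2 samples")
  stats::hclust(stats::dist(t(expr), method = "euclidean"),
                method = "complete")
}

#' Separation of high- and low-TIN samples in PC1/PC2 space
#'
#' Quantifies how well the first two principal components separate samples
#' with TIN-estimate >= +cutoff from those <= -cutoff (other samples are
#' excluded). Samples are projected on the direction connecting the two
#' group centroids in PC1/PC2 space; the score is the probability that a
#' randomly chosen high-TIN sample projects above a randomly chosen
#' low-TIN sample (a two-group ranking score / AUC): 1.0 = perfect
#' separation, 0.5 = none.
#'
#' @param pca a `pca_result` whose score rows are aligned with the TIN
#'   profile's samples.
#' @param tin a `tin_profile`.
#' @param cutoff TIN-sample cutoff (default 1.0).
#' @return separation score in \[0, 1\].
#' @export
tin_separation <- function(pca, tin, cutoff = 1.0) {
  if (nrow(pca$scores) != nrow(tin))
    stop("PCA scores and TIN profile must cover the same samples")
  hi <- tin$tin_estimate >= cutoff
  lo <- tin$tin_estimate <= -cutoff
  if (!any(hi) || !any(lo))
    stop("few samples with TIN-estimates >= ±", cutoff,
         ": both groups must be non-empty")
  k <- min(2L, ncol(pca$scores))
  s <- pca$scores[, seq_len(k), drop = FALSE]
  dir <- colMeans(s[hi, , drop = FALSE]) - colMeans(s[lo, , drop = FALSE])
  if (all(dir == 0)) return(0.5)
  proj <- as.numeric(s %*% dir)
  ph <- proj[hi]
  pl <- proj[lo]
  cmp <- outer(ph, pl, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
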