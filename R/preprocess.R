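#' Inter-chip quantile normalization
#'
#' Forces every sample (column) to share the same value distribution: each
#' value is replaced by the mean, across samples, of the order statistics at
#' its rank. Ties within a column receive the mean of the reference values
#' they span. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix, probes x samples, strictly positive linear
#'   intensities.
#' @return matrix of the same shape and dimnames, quantile-normalized.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (anyNA(x)) stop("intensity matrix must not contain missing values")
  if (any(x <= 0)) stop("intensity matrix must be strictly positive")
  if (ncol(x) < 2L) {
    warning("single-sample input: quantile normalization is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Tukey median polish of a two-way table
#'
#' Fits the additive model `value[i, j] = overall + row[i] + col[j] +
#' residual[i, j]` by alternating row and column median sweeps, rows first.
#' In the gene-model setting rows are samples (chip effects) and columns are
#' probes (probe effects). Iteration stops when the largest absolute median
#' removed in a sweep is at most `tol`, or after `max_iter` sweeps.
#'
#' @param x numeric matrix (samples x probes of log2 values), no missing
#'   cells.
#' @param max_iter maximum number of full (row + column) sweeps.
#' @param tol convergence tolerance on the largest absolute sweep median,
#'   log2 units.
#' @return a list of class `gene_model_fit` with elements `overall`, `row`
#'   (chip effects), `col` (probe effects), `residuals` (same shape as `x`),
#'   `iterations`, `converged`. The reconstruction
#'   `overall + row[i] + col[j] + residuals[i, j]` equals `x` exactly.
#' @export
median_polish <- function(x, max_iter = 10L, tol = 1e-4) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty matrix")
  if (anyNA(x)) stop("median polish requires a complete matrix")
  r <- x
  overall <- 0
  row_eff <- numeric(nrow(x))
  col_eff <- numeric(ncol(x))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rd <- apply(r, 1L, stats::median)
    r <- r - rd
    row_eff <- row_eff + rd
    d <- stats::median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    cd <- apply(r, 2L, stats::median)
    r <- sweep(r, 2L, cd)
    col_eff <- col_eff + cd
    d <- stats::median(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    if (max(abs(rd), abs(cd)) <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(overall = overall,
                 row = stats::setNames(row_eff, rownames(x)),
                 col = stats::setNames(col_eff, colnames(x)),
                 residuals = r,
                 iterations = iter,
                 converged = converged),
            class = "gene_model_fit")
}

#' Fit additive gene-level models per transcript cluster
#'
#' Log2-transforms normalized intensities and, for every transcript cluster
#' in the annotation, runs a median polish over the samples x probes table
#' of that cluster. Clusters are fitted independently. The fit per cluster
#' carries chip effects (per sample), probe effects (per probe) and the
#' residual matrix from which FIRMA scores are later summarized.
#'
#' @param normalized numeric matrix probes x samples of (quantile-
#'   normalized) linear intensities with probe ids as rownames.
#' @param annotation data.frame with columns `probe_id`, `probeset_id`,
#'   `transcript_cluster_id`; must cover every probe in `normalized`.
#' @param max_iter,tol passed to [median_polish()].
#' @param background_offset optional constant subtracted from the linear
#'   intensities before the log2 transform (a crude background correction);
#'   default 0 (none).
#' @return named list (one element per transcript cluster) of class
#'   `gene_model_fits`; each element is a `gene_model_fit` augmented with
#'   `probe_ids` and `probeset_ids` aligned to its probe columns.
#' @export
fit_gene_models <- function(normalized, annotation, max_iter = 10L,
                            tol = 1e-4, background_offset = 0) {
  if (is.null(rownames(normalized)))
    stop("normalized matrix must carry probe ids as rownames")
  missing_probes <- setdiff(rownames(normalized), annotation$probe_id)
  if (length(missing_probes) > 0L)
    stop("probe(s) without annotation: ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  vals <- normalized - background_offset
  if (any(vals <= 0))
    stop("background offset leaves non-positive intensities")
  lvals <- log2(vals)
  ann <- annotation[match(rownames(normalized), annotation$probe_id), ]
  idx_by_cluster <- split(seq_len(nrow(lvals)), ann$transcript_cluster_id)
  fits <- lapply(idx_by_cluster, function(idx) {
    tab <- t(lvals[idx, , drop = FALSE])   # samples x probes
    fit <- median_polish(tab, max_iter = max_iter, tol = tol)
    fit$probe_ids <- ann$probe_id[idx]
    fit$probeset_ids <- ann$probeset_id[idx]
    fit
  })
  structure(fits, class = "gene_model_fits",
            sample_ids = colnames(normalized))
}

#' Gene-level expression from fitted gene models
#'
#' The RMA-style gene-level summary: expression of gene g in sample i is
#' `overall + chip_effect[i]` from that gene's median-polish fit.
#'
#' @param fits a `gene_model_fits` object from [fit_gene_models()].
#' @param sample_ids optional sample ordering; defaults to the order used
#'   at fit time.
#' @return numeric matrix genes (transcript clusters) x samples, log2 scale.
#' @export
gene_level_expression <- function(fits, sample_ids = NULL) {
  if (length(fits) == 0L) stop("no fitted gene models")
  if (is.null(sample_ids)) sample_ids <- attr(fits, "sample_ids")
  expr <- t(vapply(fits, function(f) f$overall + f$row[sample_ids],
                   numeric(length(sample_ids))))
  dimnames(expr) <- list(names(fits), sample_ids)
  expr
}
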