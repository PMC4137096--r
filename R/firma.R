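#' FIRMA exon-level splicing scores
#'
#' Summarizes gene-model residuals into one splicing score per probeset
#' (exon) and sample: the median over that probeset's probes of the
#' median-polish residuals. Scores live on the log2 scale of the fitted
#' model. Strong positive scores reflect differential exon inclusion,
#' strong negative scores differential skipping, relative to the gene-level
#' expression of the rest of the samples.
#'
#' @param fits a `gene_model_fits` object from [fit_gene_models()].
#' @param annotation optional annotation data.frame; probesets listed there
#'   but absent from the fitted data are reported in a warning (they get no
#'   row). If omitted, the probesets present in the fits define the rows.
#' @return numeric matrix probesets x samples of FIRMA scores (log2), with
#'   attribute `source_dataset` if set downstream.
#' @export
firma_scores <- function(fits, annotation = NULL) {
  if (length(fits) == 0L) stop("no fitted gene models")
  sample_ids <- attr(fits, "sample_ids")
  blocks <- lapply(fits, function(f) {
    groups <- split(seq_along(f$probeset_ids), f$probeset_ids)
    res <- f$residuals   # samples x probes
    out <- vapply(groups, function(cols)
      apply(res[, cols, drop = FALSE], 1L, stats::median),
      numeric(nrow(res)))
    t(out)               # probesets x samples
  })
  scores <- do.call(rbind, blocks)
  colnames(scores) <- sample_ids
  # zap float dust from the polish sweeps: scores this small are far below
  # any meaningful log2 residual and would otherwise make exact-zero
  # (noise-free) inputs straddle percentile thresholds
  scores[abs(scores) < 1e-12] <- 0
  if (!is.null(annotation)) {
    missing <- setdiff(unique(annotation$probeset_id), rownames(scores))
    if (length(missing) > 0L)
      warning(length(missing), " annotated probeset(s) without probes in ",
              "the data were dropped: ",
              paste(utils::head(missing, 5L), collapse = ", "))
    scores <- scores[intersect(unique(annotation$probeset_id),
                               rownames(scores)), , drop = FALSE]
  }
  scores
}
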