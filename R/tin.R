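#' Dataset-wide aberrance thresholds from pooled FIRMA scores
#'
#' Computes the lower and upper percentile cutoffs (defaults: 1st and 99th)
#' of the pooled set of all exon x sample FIRMA scores in a dataset. Exons
#' below the lower threshold in a sample are called aberrantly skipped,
#' above the upper threshold aberrantly included. Uses the
#' linear-interpolation quantile convention (`type = 7`).
#'
#' @param scores FIRMA score matrix (probesets x samples).
#' @param lower_percentile,upper_percentile percentiles in (0, 100),
#'   `lower_percentile < upper_percentile`.
#' @return list of class `aberrance_thresholds` with elements `lower`,
#'   `upper`, `lower_percentile`, `upper_percentile`.
#' @export
compute_thresholds <- function(scores, lower_percentile = 1,
                               upper_percentile = 99) {
  v <- as.numeric(scores)
  if (length(v) == 0L) stop("empty score matrix")
  if (lower_percentile <= 0 || upper_percentile >= 100 ||
      lower_percentile >= upper_percentile)
    stop("percentiles must satisfy 0 < lower < upper < 100")
  if (length(v) < 100 / lower_percentile)
    warning("fewer than ", ceiling(100 / lower_percentile),
            " scores: thresholds rest on extreme order statistics")
  q <- stats::quantile(v, c(lower_percentile, upper_percentile) / 100,
                       names = FALSE, type = 7)
  if (q[1] >= q[2])
    warning("degenerate score distribution: lower threshold not below ",
            "upper threshold")
  structure(list(lower = q[1], upper = q[2],
                 lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile),
            class = "aberrance_thresholds")
}

#' Per-sample aberrant exon counts
#'
#' Counts, for every sample, the exons whose FIRMA score strictly exceeds
#' the aberrance thresholds: `skip_count` = scores below `lower`,
#' `incl_count` = scores above `upper`. Scores exactly at a threshold are
#' not counted.
#'
#' @param scores FIRMA score matrix (probesets x samples).
#' @param thresholds an `aberrance_thresholds` object (normally computed
#'   from this same score matrix).
#' @return data.frame with columns `sample_id`, `skip_count`, `incl_count`.
#' @export
count_aberrant_exons <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "aberrance_thresholds"))
  data.frame(
    sample_id = colnames(scores),
    skip_count = colSums(scores < thresholds$lower),
    incl_count = colSums(scores > thresholds$upper),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Sample-wise TIN-estimates from aberrant exon counts
#'
#' The TIN-estimate of a sample is the log2 ratio of its total aberrant
#' exon count (skipping + inclusion) to the arithmetic dataset mean of the
#' totals: a sample with twice the average aberrance has TIN-estimate
#' exactly +1.0, half the average exactly -1.0. Samples with
#' `|TIN-estimate| >= tin_cutoff` are flagged as TIN-samples. Zero counts
#' are replaced by a 0.5 pseudocount before any ratio (the dataset mean is
#' taken over the adjusted counts, so `mean(2^tin_estimate) == 1` holds
#' exactly).
#'
#' @param counts data.frame from [count_aberrant_exons()] (columns
#'   `sample_id`, `skip_count`, `incl_count`).
#' @param tin_cutoff log2 cutoff for TIN-sample designation (default 1.0).
#' @param mode `"total"` (default): TIN-estimate = log2(total / mean total).
#'   `"sum_components"`: the sum of the relative skip and inclusion log2
#'   ratios instead.
#' @param pseudocount replacement for zero counts (default 0.5).
#' @return data.frame of class `tin_profile` with columns `sample_id`,
#'   `skip_count`, `incl_count`, `total_count`, `rel_skip`, `rel_incl`,
#'   `tin_estimate`, `is_tin_sample`; attributes `tin_range` (max - min
#'   TIN-estimate), `tin_cutoff`, `mode`.
#' @export
compute_tin_estimates <- function(counts, tin_cutoff = 1.0,
                                  mode = c("total", "sum_components"),
                                  pseudocount = 0.5) {
  mode <- match.arg(mode)
  req <- c("sample_id", "skip_count", "incl_count")
  if (!all(req %in% names(counts)))
    stop("counts must have columns sample_id, skip_count, incl_count")
  if (nrow(counts) < 2L) stop("TIN-estimates need at least 2 samples")
  skip <- counts$skip_count
  incl <- counts$incl_count
  total <- skip + incl
  if (all(total == 0)) stop("all samples have zero aberrant exon counts")
  subst <- function(x) {
    if (any(x == 0)) {
      message(sum(x == 0), " zero count(s) replaced by pseudocount ",
              pseudocount)
      x[x == 0] <- pseudocount
    }
    x
  }
  skip_a <- subst(skip)
  incl_a <- subst(incl)
  total_a <- subst(total)
  rel_skip <- log2(skip_a / mean(skip_a))
  rel_incl <- log2(incl_a / mean(incl_a))
  tin <- if (mode == "total") log2(total_a / mean(total_a)) else
    rel_skip + rel_incl
  out <- data.frame(
    sample_id = counts$sample_id,
    skip_count = skip, incl_count = incl, total_count = total,
    rel_skip = rel_skip, rel_incl = rel_incl,
    tin_estimate = tin,
    is_tin_sample = abs(tin) >= tin_cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("tin_profile", "data.frame"),
            tin_range = max(tin) - min(tin),
            tin_cutoff = tin_cutoff, mode = mode)
}
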