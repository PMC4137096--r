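# Association statistic for a fixed expression submatrix against a TIN
# vector: the internal fast path shared by the resampling nulls.
set_statistic <- function(x, tin_vec, statistic, alpha = 0.05) {
  cp <- cor_with_p(x, tin_vec)
  ok <- !cp$degenerate
  r <- cp$r[ok]
  p <- cp$p[ok]
  if (length(r) == 0L) return(NA_real_)
  switch(statistic,
    pct_significant = 100 * mean(p < alpha),
    neg_pos_ratio = {
      n_neg <- sum(p < alpha & r < 0)
      n_pos <- sum(p < alpha & r > 0)
      if (n_neg + n_pos == 0L) NA_real_ else n_neg / n_pos
    },
    mean_abs_r = mean(abs(r)),
    stop("unknown statistic: ", statistic)
  )
}

#' Empirical p-value from a resampled null distribution
#'
#' The add-one estimator `p = (b + 1) / (B + 1)` where `b` counts null
#' values as or more extreme than the observed statistic in the stated
#' direction (ties count as extreme). Never returns 0; with B = 1,000 the
#' smallest attainable value is 1/1001.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of B resampled statistics.
#' @param direction `"greater"` (default) or `"less"`.
#' @return empirical p in \[1/(B+1), 1\].
#' @export
empirical_p <- function(observed, null_values,
                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0L) stop("empty null distribution")
  b <- if (direction == "greater") sum(null_values >= observed) else
    sum(null_values <= observed)
  (b + 1) / (length(null_values) + 1)
}

new_null_distribution <- function(statistic, observed, null_values,
                                  direction, seed) {
  structure(list(statistic_name = statistic,
                 observed = observed,
                 null_values = null_values,
                 B = length(null_values),
                 direction = direction,
                 empirical_p = empirical_p(observed, null_values, direction),
                 seed = seed),
            class = "null_distribution")
}

#' Permutation null for the TIN-association statistic
#'
#' Recomputes the chosen association statistic for a fixed gene set under
#' B uniform permutations of the TIN-estimate vector across samples; the
#' observed value comes from the unpermuted data. Deterministic given
#' `seed`.
#'
#' @param expr gene expression matrix (genes x samples).
#' @param tin a `tin_profile` aligned with `expr` columns.
#' @param gene_set character vector of gene ids (the focal set).
#' @param statistic one of `"pct_significant"`, `"neg_pos_ratio"`,
#'   `"mean_abs_r"`.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param alpha significance level inside the statistic.
#' @param direction comparison direction for the empirical p.
#' @return a `null_distribution` object.
#' @export
permutation_null <- function(expr, tin, gene_set,
                             statistic = "pct_significant", B = 1000L,
                             seed = 1L, alpha = 0.05,
                             direction = "greater") {
  if (B < 1L) stop("B must be >= 1")
  if (!identical(colnames(expr), tin$sample_id))
    stop("expression matrix and TIN profile must share identical, aligned ",
         "sample ids")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0L) stop("no gene-set member present in expr")
  x <- expr[present, , drop = FALSE]
  tv <- tin$tin_estimate
  observed <- set_statistic(x, tv, statistic, alpha)
  set.seed(seed)
  nulls <- vapply(seq_len(B), function(b)
    set_statistic(x, tv[sample.int(length(tv))], statistic, alpha),
    numeric(1))
  new_null_distribution(statistic, observed, nulls, direction, seed)
}

#' Random-gene-set null for the TIN-association statistic
#'
#' Recomputes the chosen statistic for B gene sets of matched size drawn
#' uniformly without replacement from the full gene universe (the focal
#' set's genes are not excluded), with the TIN vector fixed. The observed
#' value comes from the focal gene set.
#'
#' @inheritParams permutation_null
#' @param set_size size of each random set; defaults to the number of
#'   focal-set genes present in `expr`.
#' @param universe gene universe to draw from; defaults to all genes in
#'   `expr`.
#' @return a `null_distribution` object.
#' @export
random_geneset_null <- function(expr, tin, gene_set,
                                statistic = "pct_significant",
                                B = 1000L, seed = 1L, alpha = 0.05,
                                set_size = NULL,
                                universe = rownames(expr),
                                direction = "greater") {
  if (B < 1L) stop("B must be >= 1")
  if (!identical(colnames(expr), tin$sample_id))
    stop("expression matrix and TIN profile must share identical, aligned ",
         "sample ids")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0L) stop("no gene-set member present in expr")
  if (is.null(set_size)) set_size <- length(present)
  universe <- intersect(universe, rownames(expr))
  if (set_size > length(universe))
    stop("set_size exceeds the gene universe (", length(universe), ")")
  if (set_size == length(universe))
    warning("set_size equals the universe: the null has zero variance")
  tv <- tin$tin_estimate
  observed <- set_statistic(expr[present, , drop = FALSE], tv, statistic,
                            alpha)
  set.seed(seed)
  nulls <- vapply(seq_len(B), function(b) {
    draw <- sample(universe, set_size)
    set_statistic(expr[draw, , drop = FALSE], tv, statistic, alpha)
  }, numeric(1))
  new_null_distribution(statistic, observed, nulls, "greater", seed)
}

#' Association summaries for a battery of gene sets
#'
#' One [summarize_association()] row per gene set with at least two member
#' genes present in the expression matrix, plus a whole-genome row over all
#' genes. Sets with fewer than two present genes are skipped and reported.
#' When a focal set is named, its rank among all sets (whole-genome row
#' excluded) by decreasing `pct_significant` is attached.
#'
#' @param expr gene expression matrix (genes x samples).
#' @param tin aligned `tin_profile`.
#' @param genesets list of gene sets (`list(name, description, genes)`), as
#'   returned by [read_gmt()] or [generate_dataset()].
#' @param alpha significance level.
#' @param focal optional name of the focal set to rank.
#' @return data.frame of summary rows (last row `WHOLE_GENOME`); attributes
#'   `skipped_sets` and, if `focal` given, `focal_rank`.
#' @export
geneset_battery <- function(expr, tin, genesets, alpha = 0.05,
                            focal = NULL) {
  if (length(genesets) == 0L) stop("empty gene-set collection")
  rows <- list()
  skipped <- character()
  for (gs in genesets) {
    present <- intersect(gs$genes, rownames(expr))
    if (length(present) < 2L) {
      skipped <- c(skipped, gs$name)
      next
    }
    rec <- correlate_genes_with_tin(expr, tin, gs$genes, alpha)
    rows[[gs$name]] <- summarize_association(rec, alpha, set_name = gs$name)
  }
  if (length(rows) == 0L) stop("no gene set with >= 2 genes present in expr")
  if (length(skipped) > 0L)
    warning("skipped set(s) with < 2 genes present: ",
            paste(skipped, collapse = ", "))
  genome <- summarize_association(
    correlate_genes_with_tin(expr, tin, rownames(expr), alpha),
    alpha, set_name = "WHOLE_GENOME")
  out <- rbind(do.call(rbind, rows), genome)
  rownames(out) <- NULL
  attr(out, "skipped_sets") <- skipped
  if (!is.null(focal)) {
    sets <- out[out$set_name != "WHOLE_GENOME", ]
    attr(out, "focal_rank") <-
      match(focal, sets$set_name[order(-sets$pct_significant)])
  }
  out
}
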