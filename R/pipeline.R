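#' Bundle a dataset's inputs
#'
#' Light container tying together a dataset's intensities, annotation,
#' gene sets and sample metadata, validated for consistency.
#'
#' @param name dataset label.
#' @param intensities probe x sample matrix, linear scale, probe ids as
#'   rownames.
#' @param annotation annotation data.frame covering all probes.
#' @param genesets list of gene sets (`list(name, description, genes)`).
#' @param metadata optional sample table (`sample_id`, `group`, `pair_id`).
#' @return list of class `dataset_bundle`.
#' @export
dataset_bundle <- function(name, intensities, annotation, genesets = list(),
                           metadata = NULL) {
  missing_probes <- setdiff(rownames(intensities), annotation$probe_id)
  if (length(missing_probes) > 0L)
    stop("annotation does not cover probe(s): ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  if (!is.null(metadata) &&
      !all(metadata$sample_id %in% colnames(intensities)))
    stop("metadata sample ids must be a subset of intensity sample ids")
  structure(list(name = name, intensities = intensities,
                 annotation = annotation, genesets = genesets,
                 metadata = metadata),
            class = "dataset_bundle")
}

default_config <- function(config = list()) {
  defaults <- list(
    polish = list(max_iter = 10L, tol = 1e-4),
    background = list(offset = 0),
    tin = list(lower_percentile = 1, upper_percentile = 99, cutoff = 1.0,
               mode = "total", pseudocount = 0.5),
    alpha = 0.05,
    statistic = "pct_significant",
    B = 1000L,
    seed = 1L,
    run_nulls = TRUE,
    run_multivariate = TRUE
  )
  utils::modifyList(defaults, config)
}

#' Run the full single-dataset TIN analysis
#'
#' Executes the whole pipeline on one dataset: quantile normalization,
#' gene-model fits by median polish, FIRMA scores, pooled percentile
#' thresholds, aberrant exon counts, TIN-estimates, gene-level expression,
#' per-gene-set association summaries, permutation and random-gene-set
#' nulls for the first (focal) gene set, and PCA / hierarchical clustering
#' on the focal-set genes. Expression and FIRMA scores derive from the same
#' normalized fit. Deterministic given `config$seed`.
#'
#' @param bundle a [dataset_bundle()].
#' @param config named list overriding entries of the default
#'   configuration: `polish$max_iter`, `polish$tol`, `background$offset`,
#'   `tin$lower_percentile`, `tin$upper_percentile`, `tin$cutoff`,
#'   `tin$mode`, `alpha`, `statistic`, `B`, `seed`, and the switches
#'   `run_nulls`, `run_multivariate`.
#' @return list of class `tin_report` with elements `dataset`,
#'   `thresholds`, `tin`, `expression`, `firma`, `correlations`,
#'   `summaries`, `nulls` (permutation + random gene sets), `pca`,
#'   `clustering`, `separation`, `provenance`.
#' @export
run_dataset_analysis <- function(bundle, config = list()) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  cfg <- default_config(config)
  message("[", bundle$name, "] quantile normalization of ",
          nrow(bundle$intensities), " probes x ",
          ncol(bundle$intensities), " samples")
  normalized <- quantile_normalize(bundle$intensities)
  message("[", bundle$name, "] fitting gene models")
  fits <- fit_gene_models(normalized, bundle$annotation,
                          max_iter = cfg$polish$max_iter,
                          tol = cfg$polish$tol,
                          background_offset = cfg$background$offset)
  scores <- firma_scores(fits, bundle$annotation)
  thresholds <- compute_thresholds(scores, cfg$tin$lower_percentile,
                                   cfg$tin$upper_percentile)
  message(sprintf("[%s] thresholds: lower %.3f, upper %.3f", bundle$name,
                  thresholds$lower, thresholds$upper))
  counts <- count_aberrant_exons(scores, thresholds)
  tin <- compute_tin_estimates(counts, tin_cutoff = cfg$tin$cutoff,
                               mode = cfg$tin$mode,
                               pseudocount = cfg$tin$pseudocount)
  expr <- gene_level_expression(fits)

  correlations <- list()
  summaries <- list()
  nulls <- list()
  pca <- NULL
  clustering <- NULL
  separation <- NA_real_
  if (length(bundle$genesets) > 0L) {
    for (gs in bundle$genesets) {
      rec <- correlate_genes_with_tin(expr, tin, gs$genes, cfg$alpha)
      correlations[[gs$name]] <- rec
      summaries[[gs$name]] <- summarize_association(rec, cfg$alpha,
                                                    set_name = gs$name)
    }
    focal <- bundle$genesets[[1]]
    if (isTRUE(cfg$run_nulls)) {
      message("[", bundle$name, "] resampling nulls (B = ", cfg$B, ")")
      nulls$permutation <- permutation_null(
        expr, tin, focal$genes, statistic = cfg$statistic, B = cfg$B,
        seed = cfg$seed, alpha = cfg$alpha)
      nulls$random_genesets <- random_geneset_null(
        expr, tin, focal$genes, statistic = cfg$statistic, B = cfg$B,
        seed = cfg$seed + 1L, alpha = cfg$alpha)
    }
    if (isTRUE(cfg$run_multivariate)) {
      sf_expr <- expr[intersect(focal$genes, rownames(expr)), ,
                      drop = FALSE]
      pca <- pca_covariance(sf_expr)
      clustering <- hierarchical_clustering(sf_expr)
      separation <- tryCatch(tin_separation(pca, tin, cfg$tin$cutoff),
                             error = function(e) {
                               warning(conditionMessage(e))
                               NA_real_
                             })
    }
  }
  structure(list(dataset = bundle$name,
                 thresholds = thresholds,
                 tin = tin,
                 expression = expr,
                 firma = scores,
                 correlations = correlations,
                 summaries = summaries,
                 nulls = nulls,
                 pca = pca,
                 clustering = clustering,
                 separation = separation,
                 provenance = list(seed = cfg$seed, config = cfg,
                                   version = as.character(
                                     utils::packageVersion("tinscope")))),
            class = "tin_report")
}

#' Pooled (pan-cancer) TIN analysis across datasets
#'
#' Randomly selects `n_per_dataset` samples from every bundle (without
#' replacement, per-bundle seeds derived from the root seed so the draw is
#' order-independent), pools the intensity matrices, and reruns the entire
#' pipeline — normalization, FIRMA, thresholds and TIN-estimates are all
#' recomputed across the pooled samples, not concatenated from per-dataset
#' runs. The first bundle's gene sets are used for the pooled association.
#'
#' @param bundles list of [dataset_bundle()]s sharing one annotation
#'   scheme (identical probe ids).
#' @param n_per_dataset samples to draw from each bundle.
#' @param seed root seed for the subsampling.
#' @param config passed to [run_dataset_analysis()].
#' @return a `tin_report` for the pooled dataset; the attached metadata
#'   records each sample's dataset of origin.
#' @export
run_pan_cancer <- function(bundles, n_per_dataset, seed = 1L,
                           config = list()) {
  if (length(bundles) < 2L) stop("pooled analysis needs >= 2 bundles")
  probe_ids <- rownames(bundles[[1]]$intensities)
  for (b in bundles) {
    if (ncol(b$intensities) < n_per_dataset)
      stop("bundle '", b$name, "' has fewer than ", n_per_dataset,
           " samples")
    if (!identical(rownames(b$intensities), probe_ids))
      stop("bundle '", b$name, "' does not share the annotation scheme")
  }
  picked <- lapply(seq_along(bundles), function(i) {
    set.seed(seed + i)
    b <- bundles[[i]]
    cols <- sort(sample.int(ncol(b$intensities), n_per_dataset))
    m <- b$intensities[, cols, drop = FALSE]
    colnames(m) <- paste(b$name, colnames(m), sep = ".")
    m
  })
  pooled <- do.call(cbind, picked)
  metadata <- data.frame(
    sample_id = colnames(pooled),
    dataset = rep(vapply(bundles, `[[`, character(1), "name"),
                  each = n_per_dataset),
    stringsAsFactors = FALSE
  )
  bundle <- dataset_bundle(
    name = paste0("pooled(", length(bundles), "x", n_per_dataset, ")"),
    intensities = pooled,
    annotation = bundles[[1]]$annotation,
    genesets = bundles[[1]]$genesets,
    metadata = metadata
  )
  config$seed <- if (is.null(config$seed)) seed else config$seed
  run_dataset_analysis(bundle, config)
}
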