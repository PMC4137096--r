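#' Read a matrix from tab-delimited text
#'
#' First column holds row identifiers, remaining columns numeric values,
#' header row holds column identifiers. Duplicate ids and non-numeric cells
#' are refused with the offending line.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0L)
    stop("duplicate row id '", ids[dup[1]], "' at line ", dup[1] + 1L,
         " of ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow = nrow(m)))) & !is.na(m),
      arr.ind = TRUE)
    stop("non-numeric cell at line ", bad[1, 1] + 1L, ", column ",
         bad[1, 2] + 1L, " of ", path)
  }
  rownames(m) <- ids
  m
}

#' Write a matrix as tab-delimited text
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param id_col header name of the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "probe_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path file path.
#' @return list of gene sets, each `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " (need name, description, >=1 gene)")
    list(name = f[1], description = f[2], genes = f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name in ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param genesets list of `list(name, description, genes)`.
#' @param path output path.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(genesets, function(gs)
    paste(c(gs$name, gs$description, gs$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Tab-delimited with columns `probe_id`, `probeset_id`,
#' `transcript_cluster_id`. Each probe must appear exactly once and each
#' probeset must map to exactly one transcript cluster.
#'
#' @param path file path.
#' @return annotation data.frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "probeset_id", "transcript_cluster_id")
  if (!all(req %in% names(ann)))
    stop("annotation must have columns ", paste(req, collapse = ", "))
  dup <- which(duplicated(ann$probe_id))
  if (length(dup) > 0L)
    stop("probe '", ann$probe_id[dup[1]], "' listed twice (line ",
         dup[1] + 1L, " of ", path, ")")
  multi <- tapply(ann$transcript_cluster_id, ann$probeset_id,
                  function(x) length(unique(x)))
  if (any(multi > 1L))
    stop("probeset(s) mapped to multiple transcript clusters: ",
         paste(utils::head(names(multi)[multi > 1L], 5L), collapse = ", "))
  ann
}

#' Read a sample metadata table
#'
#' Tab-delimited with a `sample_id` column and optional `group` /
#' `pair_id` columns.
#'
#' @param path file path.
#' @return metadata data.frame.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop("metadata must have a sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in ", path)
  md
}
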