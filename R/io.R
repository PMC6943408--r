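# Plain-text readers and writers for the pipeline's standard formats:
# OTU counts (features x samples TSV), taxonomy, metadata, survey,
# physiology, guild rules, distance matrices, Newick trees.

#' Write / read a plain TSV table
#'
#' Minimal wrappers around [utils::write.table()] / [utils::read.table()]
#' with the conventions used throughout the pipeline: tab-separated,
#' header row, no quoting, no row names, names kept verbatim.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param ... further arguments passed to [utils::read.table()].
#' @return `path` invisibly (write) or a data.frame (read).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write / read an OTU table as TSV
#'
#' On disk the table is features x samples with a leading `feature_id`
#' column and a header row of sample ids; in memory it is the samples x
#' features matrix the analysis functions use.
#'
#' @param table samples x features matrix.
#' @param path file path.
#' @return `path` (write) or the counts matrix (read).
#' @export
write_otu_tsv <- function(table, path) {
  table <- otu_table(table)
  df <- data.frame(feature_id = colnames(table), t(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path) {
  df <- read_tsv(path)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$feature_id
  otu_table(m)
}

#' Write / read a taxonomy table as TSV
#'
#' Written as `feature_id` plus a semicolon-delimited seven-rank
#' `lineage`; read back into rank columns via [parse_taxonomy()].
#'
#' @param taxonomy taxonomy data.frame with rank columns.
#' @param path file path.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  rk <- rank_names()
  lin <- apply(taxonomy[, rk], 1, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = ";")
  })
  write_tsv(data.frame(feature_id = taxonomy$feature_id, lineage = lin,
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path) parse_taxonomy(read_tsv(path))

#' Write a square distance matrix as TSV
#' @param d distance matrix.
#' @param path file path.
#' @export
write_distance_tsv <- function(d, path) {
  d <- check_distance(d)
  write_tsv(data.frame(sample_id = rownames(d), d, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  check_distance(m)
}
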