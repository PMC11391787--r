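#' @name io
#' @title TSV readers/writers for graph and result tables
#' @description
#' All tables are UTF-8, tab-separated with a header row — TCM labels
#' routinely contain commas, so TSV avoids quoting headaches. Readers
#' validate headers and referential integrity and report offending rows;
#' writers round-trip exactly with the readers.
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stopf("%s file not found: %s", what, path, class = "prescsim_io_error")
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("%s: header lacks column(s) %s", path,
          paste(missing, collapse = ", "), class = "prescsim_io_error")
  df
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a node table (id, node_type, label, role)
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_node_table <- function(path) {
  validate_node_table(read_tsv_checked(path, c("id", "node_type", "label"),
                                       "node"))
}

#' Read an edge table (source, target, relation)
#' @param path TSV file path.
#' @param nodes optional node table; when given, referential and
#'   type-signature checks run immediately with row numbers in errors.
#' @return data.frame.
#' @export
read_edge_table <- function(path, nodes = NULL) {
  edges <- read_tsv_checked(path, c("source", "target", "relation"), "edge")
  if (!is.null(nodes)) edges <- validate_edge_table(edges, nodes)
  edges
}

#' Read a prescription annotation table
#'
#' Columns: `prescription_id` plus logical `pediatric` and
#' `respiratory_only` flags used by [apply_exclusions()].
#' @param path TSV file path.
#' @return data.frame with logical flag columns.
#' @export
read_annotation_table <- function(path) {
  ann <- read_tsv_checked(path, c("prescription_id", "pediatric",
                                  "respiratory_only"), "annotation")
  ann$pediatric <- as.logical(ann$pediatric)
  ann$respiratory_only <- as.logical(ann$respiratory_only)
  ann
}

#' Write / read a similarity table
#'
#' Values are written with six decimal places; `read_similarity_table()`
#' restores the `similarity_table` class.
#' @param table a `similarity_table`.
#' @param path TSV file path.
#' @return the path (write) or the table (read), invisibly for writes.
#' @export
write_similarity_table <- function(table, path) {
  out <- table
  out$value <- sprintf("%.6f", out$value)
  write_tsv(out, path)
}

#' @rdname write_similarity_table
#' @export
read_similarity_table <- function(path) {
  df <- read_tsv_checked(path, c("target_id", "candidate_id", "metric",
                                 "value"), "similarity")
  df$value <- as.numeric(df$value)
  class(df) <- c("similarity_table", "data.frame")
  df
}

#' Write node/edge tables
#' @param nodes,edges data.frames in the package's TSV dialect.
#' @param path TSV file path.
#' @return the path, invisibly.
#' @export
write_node_table <- function(nodes, path) write_tsv(nodes, path)

#' @rdname write_node_table
#' @export
write_edge_table <- function(edges, path) write_tsv(edges, path)

#' Write summary statistics as JSON
#' @param stats a `summary_stats` object (or named list of them).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(lapply(unclass(stats), unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a screen report (retained + excluded pairs with reasons)
#' @param result a `screen_result`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_screen_report <- function(result, path) {
  retained <- result$pairs
  if (nrow(retained)) retained$status <- "retained"
  else retained$status <- character(0)
  if (nrow(retained)) retained$reason <- ""
  else retained$reason <- character(0)
  excluded <- result$excluded
  if (nrow(excluded)) excluded$status <- "excluded"
  else excluded$status <- character(0)
  out <- rbind(retained[, c("target_id", "candidate_id", "metric", "value",
                            "status", "reason")],
               excluded[, c("target_id", "candidate_id", "metric", "value",
                            "status", "reason")])
  out$value <- sprintf("%.6f", out$value)
  write_tsv(out, path)
}

#' Write embeddings as TSV (node_id + d numeric columns)
#' @param embeddings an `embedding_set`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(node_id = embeddings$node_ids,
                   as.data.frame(unname(embeddings$H)))
  names(df) <- c("node_id", sprintf("dim_%d", seq_len(ncol(embeddings$H))))
  write_tsv(df, path)
}

#' Load reference pairwise similarity values
#'
#' The study's raw similarity values (1340 cosine + 1340 Jaccard) are
#' distributed as journal supplementary data, not bundled here. Place them,
#' converted to the package's similarity-table TSV dialect (`target_id`,
#' `candidate_id`, `metric`, `value`), at
#' `inst/extdata/additional-file-1-similarities.tsv` (or pass any path) to
#' reproduce the published summary statistics and screen counts.
#'
#' @param path TSV path; defaults to the bundled drop-in location.
#' @return a `similarity_table`.
#' @export
load_reference_similarities <- function(path = system.file(
    "extdata", "additional-file-1-similarities.tsv", package = "prescsim")) {
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stopf(paste("reference similarity values not found; the supplementary",
                "data file must be supplied separately (see ?load_reference_similarities)"),
          class = "prescsim_io_error")
  read_similarity_table(path)
}
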