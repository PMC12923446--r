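# TSV dialects. Every artifact starts with a comment header recording the
# package version, the seed, and a hash of the run configuration; readers
# skip '#' lines. Numeric columns are written with %.17g so write-then-read
# round-trips to full double precision.

fnv1a <- function(s) {
  # polynomial rolling hash in doubles (base-R bitwXor is 32-bit-signed)
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", h)
}

artifact_header <- function(seed = NA, config = "") {
  sprintf("# signgenie %s seed=%s config=%s", .sgn_version(),
          if (is.na(seed)) "NA" else as.character(seed), fnv1a(config))
}

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_artifact <- function(df, path, seed = NA, config = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

read_tsv_artifact <- function(path, colClasses = NA) {
  if (!file.exists(path))
    sgn_stop("file not found: ", path, class = "sgn_io_error")
  read.delim(path, comment.char = "#", sep = "\t", header = TRUE,
             colClasses = colClasses, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read an expression matrix and cell metadata into a dataset
#'
#' The expression TSV has a header of gene names and one row per cell, first
#' column `cell_id`. The metadata TSV has columns `cell_id`, `pseudotime`
#' (empty for steady-state cells) and optionally `condition`. Every metadata
#' cell id must exist in the expression table and vice versa.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the metadata TSV.
#' @param stimulus enable the stimulus indicator column.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(expr_path, meta_path, stimulus = FALSE) {
  ex <- read_tsv_artifact(expr_path)
  if (names(ex)[1] != "cell_id")
    sgn_stop("expression file must have 'cell_id' as its first column (",
             expr_path, ")", class = "sgn_io_error")
  meta <- read_tsv_artifact(meta_path,
                            colClasses = c(cell_id = "character"))
  for (col in c("cell_id", "pseudotime"))
    if (!col %in% names(meta))
      sgn_stop("metadata is missing column '", col, "' (", meta_path, ")",
               class = "sgn_io_error")
  unknown <- setdiff(meta$cell_id, ex$cell_id)
  if (length(unknown))
    sgn_stop("metadata references unknown cell id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "),
             class = "sgn_io_error")
  missing <- setdiff(ex$cell_id, meta$cell_id)
  if (length(missing))
    sgn_stop("expression cell id(s) missing from metadata: ",
             paste(utils::head(missing, 5), collapse = ", "),
             class = "sgn_io_error")
  m <- as.matrix(ex[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(ex[-1], is.numeric, logical(1)))
    sgn_stop("non-numeric expression column(s): ",
             paste(names(ex)[-1][bad], collapse = ", "),
             class = "sgn_io_error")
  }
  rownames(m) <- ex$cell_id
  meta <- meta[match(ex$cell_id, meta$cell_id), ]
  pt <- suppressWarnings(as.numeric(meta$pseudotime))
  expression_dataset(m, pt, condition = meta$condition, stimulus = stimulus)
}

#' Write a dataset as expression + metadata TSVs
#'
#' @param data an [expression_dataset()].
#' @param expr_path,meta_path output paths.
#' @param seed seed recorded in the artifact headers.
#' @export
write_expression <- function(data, expr_path, meta_path, seed = NA) {
  cfg <- paste0("genes=", ncol(data$expr), ";cells=", nrow(data$expr))
  ex <- data.frame(cell_id = rownames(data$expr),
                   apply(data$expr, 2, fmt_num), check.names = FALSE)
  write_tsv_artifact(ex, expr_path, seed, cfg)
  meta <- data.frame(
    cell_id = rownames(data$expr),
    pseudotime = ifelse(is.na(data$pseudotime), "",
                        fmt_num(data$pseudotime)),
    condition = if (is.null(data$condition)) "" else data$condition)
  write_tsv_artifact(meta, meta_path, seed, cfg)
  invisible(data)
}

#' Write a label table
#' @param labels data.frame from [label_table()].
#' @param path output TSV path.
#' @param seed seed recorded in the header.
#' @export
write_labels <- function(labels, path, seed = NA) {
  labels$weight <- fmt_num(labels$weight)
  write_tsv_artifact(labels, path, seed, paste0("rows=", nrow(labels)))
}

#' Read a label table
#' @param path TSV path written by [write_labels()].
#' @return data.frame with columns `cell_id`, `gene`, `label`, `weight`.
#' @export
read_labels <- function(path) {
  df <- read_tsv_artifact(path, colClasses = c(
    cell_id = "character", gene = "character", label = "character",
    weight = "numeric"))
  df
}

#' Write a ranked edge list
#' @param net an `sgn_network` from [infer_network()].
#' @param path output TSV path.
#' @param seed seed recorded in the header.
#' @export
write_edges <- function(net, path, seed = NA) {
  df <- as.data.frame(net)
  df$confidence <- fmt_num(df$confidence)
  write_tsv_artifact(df, path, seed, paste0("edges=", nrow(df)))
}

#' Read a ranked edge list
#' @param path TSV path written by [write_edges()].
#' @return an `sgn_network` data.frame.
#' @export
read_edges <- function(path) {
  df <- read_tsv_artifact(path, colClasses = c(
    regulator = "character", target = "character", confidence = "numeric",
    rank = "integer"))
  class(df) <- c("sgn_network", "data.frame")
  df
}

#' Read a gold-standard edge list
#'
#' Two-column TSV (`regulator`, `target`); a header row is detected and
#' optional.
#'
#' @param path TSV path.
#' @return an [gold_standard()] object.
#' @export
read_gold <- function(path) {
  if (!file.exists(path))
    sgn_stop("file not found: ", path, class = "sgn_io_error")
  first <- readLines(path, n = 10L)
  first <- first[!startsWith(first, "#")][1]
  has_header <- grepl("regulator", first, fixed = TRUE)
  df <- read.delim(path, comment.char = "#", sep = "\t",
                   header = has_header, stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("regulator", "target")
  gold_standard(df)
}

#' Write a gold-standard edge list
#' @param gold an [gold_standard()] object.
#' @param path output TSV path.
#' @param seed seed recorded in the header.
#' @export
write_gold <- function(gold, path, seed = NA) {
  write_tsv_artifact(as.data.frame(gold), path, seed,
                     paste0("edges=", nrow(gold)))
}
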