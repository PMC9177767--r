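#' Read and write the package's tables
#'
#' Tab-delimited text is the canonical interchange format: tile tables carry
#' `slide_id`, `tile_index` and `f0..f{M-1}` columns; matrices are written
#' with their row keys in column 1. Values are serialized with 17 significant
#' digits, so a text round trip reproduces doubles exactly. When the `arrow`
#' package is available the same tables can be stored in Feather, a columnar
#' binary container that round-trips bit-identically.
#'
#' @param tiles data.frame tile feature table.
#' @param path file path; `.feather` extension selects the binary container.
#' @name mone_io
NULL

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

use_feather <- function(path) grepl("\\.feather$", path)

write_table_any <- function(df, path) {
  if (use_feather(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Feather files")
    arrow::write_feather(df, path)
  } else {
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], fmt_num)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

read_table_any <- function(path) {
  if (use_feather(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Feather files")
    as.data.frame(arrow::read_feather(path))
  } else {
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
}

#' @rdname mone_io
#' @export
write_tile_table <- function(tiles, path) write_table_any(tiles, path)

#' @rdname mone_io
#' @export
read_tile_table <- function(path) read_table_any(path)

#' @rdname mone_io
#' @param x a [mone_matrix()].
#' @param meta_path path for the metadata table.
#' @export
write_mone_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "mone_matrix"))
  df <- data.frame(slide_id = x$meta$slide_id, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("slide_id", colnames(x$values))
  write_table_any(df, path)
  write_table_any(as.data.frame(x$meta), meta_path)
  invisible(path)
}

#' @rdname mone_io
#' @export
read_mone_matrix <- function(path, meta_path) {
  df <- read_table_any(path)
  md <- read_table_any(meta_path)
  meta <- slide_meta(md$slide_id, md$patient_id, md$cancer_type, md$lesion,
                     md$preparation, md$vial_id)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$slide_id
  vals <- vals[match(meta$slide_id, rownames(vals)), , drop = FALSE]
  mone_matrix(vals, meta)
}

#' @rdname mone_io
#' @param expr an [expression_matrix()].
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(vial_id = expr$vial_id, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("vial_id", colnames(expr$values))
  write_table_any(df, path)
}

#' @rdname mone_io
#' @export
read_expression_matrix <- function(path) {
  df <- read_table_any(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  expression_matrix(vals, df$vial_id, colnames(vals))
}
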