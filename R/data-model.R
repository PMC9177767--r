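#' Slide metadata table
#'
#' Builds and validates the per-slide metadata table used throughout the
#' package. Each slide belongs to exactly one patient and carries its cancer
#' type, lesion status (tumor or adjacent normal) and tissue preparation
#' (fresh-frozen or FFPE). The `vial_id` is the sample-level key shared with
#' expression profiles and is derived from the slide id by default.
#'
#' @param slide_id character vector of unique slide identifiers.
#' @param patient_id character vector, one patient per slide.
#' @param cancer_type character vector of cancer type codes (e.g. `"BRCA"`).
#' @param lesion character vector, each `"tumor"` or `"normal"`.
#' @param preparation character vector, each `"frozen"` or `"FFPE"`.
#' @param vial_id optional character vector of sample/vial keys; derived from
#'   `slide_id` via [extract_vial_id()] when missing.
#' @return A `data.frame` with class `slide_meta`.
#' @export
slide_meta <- function(slide_id, patient_id, cancer_type, lesion, preparation,
                       vial_id = NULL) {
  slide_id <- as.character(slide_id)
  if (anyDuplicated(slide_id))
    stop("duplicated slide_id: ",
         paste(unique(slide_id[duplicated(slide_id)]), collapse = ", "))
  n <- length(slide_id)
  check_len <- function(x, nm) {
    if (length(x) != n) stop(nm, " must have length ", n)
    if (anyNA(x)) stop(nm, " contains missing values")
    as.character(x)
  }
  patient_id <- check_len(patient_id, "patient_id")
  cancer_type <- check_len(cancer_type, "cancer_type")
  lesion <- check_len(lesion, "lesion")
  preparation <- check_len(preparation, "preparation")
  if (!all(lesion %in% c("tumor", "normal")))
    stop("lesion must be 'tumor' or 'normal'")
  if (!all(preparation %in% c("frozen", "FFPE")))
    stop("preparation must be 'frozen' or 'FFPE'")
  if (is.null(vial_id)) vial_id <- extract_vial_id(slide_id)
  vial_id <- check_len(vial_id, "vial_id")
  out <- data.frame(slide_id = slide_id, patient_id = patient_id,
                    cancer_type = cancer_type, lesion = lesion,
                    preparation = preparation, vial_id = vial_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("slide_meta", "data.frame")
  out
}

#' Derive the vial-level sample key from a slide identifier
#'
#' TCGA-style slide barcodes encode
#' project-site-participant-sample+vial-portion-...; the vial key is the
#' barcode truncated after the vial letter (the first four dash-delimited
#' fields, e.g. `"TCGA-A7-A0CE-01A"`). Identifiers with fewer than four
#' fields are returned unchanged so non-TCGA naming schemes pass through and
#' can instead supply `vial_id` explicitly or a custom key function.
#'
#' @param slide_id character vector of slide identifiers.
#' @return character vector of vial keys, case-normalized to upper case with
#'   surrounding whitespace removed.
#' @export
extract_vial_id <- function(slide_id) {
  x <- toupper(trimws(as.character(slide_id)))
  parts <- strsplit(x, "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= 4) paste(p[1:4], collapse = "-") else paste(p, collapse = "-")
  }, character(1))
}

#' Slides-by-features matrix with aligned metadata
#'
#' The central container: one row per slide, one column per mone (feature).
#' Feature columns are labeled by integer mone ids `0..M-1`; row order is
#' exactly the metadata order.
#'
#' @param values numeric matrix, `n_slides x M`, no missing values.
#' @param meta a [slide_meta()] table with one row per matrix row.
#' @return An object of class `mone_matrix`: a list with elements `values`
#'   (rownames = slide ids, colnames = mone ids) and `meta`.
#' @export
mone_matrix <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!inherits(meta, "slide_meta")) stop("meta must be a slide_meta table")
  if (nrow(values) != nrow(meta))
    stop("values has ", nrow(values), " rows but meta has ", nrow(meta))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], ", column ", bad[2])
  }
  if (is.null(colnames(values))) colnames(values) <- as.character(seq_len(ncol(values)) - 1L)
  if (anyDuplicated(colnames(values))) stop("feature labels must be unique")
  rownames(values) <- meta$slide_id
  structure(list(values = values, meta = meta), class = "mone_matrix")
}

#' @export
print.mone_matrix <- function(x, ...) {
  cat("mone_matrix:", nrow(x$values), "slides x", ncol(x$values), "mones\n")
  cat("cancer types:", paste(sort(unique(x$meta$cancer_type)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mone_matrix <- function(x) dim(x$values)

#' Subset a mone matrix by slides and/or features
#'
#' @param x a `mone_matrix`.
#' @param slides logical/integer/character index over slides.
#' @param features logical/integer/character index over feature columns.
#' @return A `mone_matrix` with metadata subset in step.
#' @export
subset_mones <- function(x, slides = NULL, features = NULL) {
  stopifnot(inherits(x, "mone_matrix"))
  v <- x$values
  m <- x$meta
  if (!is.null(slides)) {
    v <- v[slides, , drop = FALSE]
    m <- m[slides, , drop = FALSE]
    class(m) <- c("slide_meta", "data.frame")
  }
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  mone_matrix(v, m)
}

#' Aggregate tile-level features into slide-level mones
#'
#' Collapses a tile feature table (one row per tile) to one row per slide by
#' taking, for each feature, the median over that slide's tiles. The sample
#' median (mean of the two central order statistics for even tile counts) is
#' the only supported statistic; the `stat` argument exists so future
#' aggregators are an explicit extension rather than a silent configuration.
#'
#' @param tiles data.frame with columns `slide_id`, `tile_index`, and feature
#'   columns `f0..f{M-1}` (any column whose name is not `slide_id` or
#'   `tile_index` is treated as a feature).
#' @param meta a [slide_meta()] table; every slide listed must have tiles.
#' @param stat aggregation statistic; only `"median"`.
#' @return A [mone_matrix()] with one row per `meta` slide, in `meta` order.
#' @export
aggregate_tiles <- function(tiles, meta, stat = c("median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(meta, "slide_meta"))
  feat_cols <- setdiff(colnames(tiles), c("slide_id", "tile_index"))
  if (length(feat_cols) == 0) stop("tile table has no feature columns")
  fmat <- as.matrix(tiles[, feat_cols, drop = FALSE])
  storage.mode(fmat) <- "double"
  if (!all(is.finite(fmat))) {
    bad <- which(!is.finite(fmat), arr.ind = TRUE)[1, ]
    stop("non-finite feature value in tile row ", bad[1],
         ", feature column ", feat_cols[bad[2]])
  }
  sid <- as.character(tiles$slide_id)
  missing <- setdiff(meta$slide_id, sid)
  if (length(missing))
    stop("slides with zero tiles: ", paste(missing, collapse = ", "))
  idx <- split(seq_along(sid), sid)
  out <- matrix(NA_real_, nrow(meta), length(feat_cols),
                dimnames = list(meta$slide_id, as.character(seq_along(feat_cols) - 1L)))
  for (i in seq_len(nrow(meta))) {
    rows <- idx[[meta$slide_id[i]]]
    block <- fmat[rows, , drop = FALSE]
    out[i, ] <- apply(block, 2L, stats::median)
  }
  mone_matrix(out, meta)
}

#' Log-normalized expression matrix
#'
#' @param values numeric matrix, samples x genes, finite log-normalized
#'   abundances (log(FPKM+1) convention).
#' @param vial_id character vector of sample keys (one per row).
#' @param genes optional character vector of unique gene symbols; defaults to
#'   existing column names.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, vial_id, genes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("expression values must be finite")
  vial_id <- toupper(trimws(as.character(vial_id)))
  if (length(vial_id) != nrow(values)) stop("one vial_id per sample row required")
  if (is.null(genes)) genes <- colnames(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  dimnames(values) <- list(vial_id, genes)
  structure(list(values = values, vial_id = vial_id), class = "expression_matrix")
}

#' Match slides to expression profiles by vial
#'
#' Pairs each slide with the expression profile from the same vial. Keys are
#' compared as exact strings after upper-casing and whitespace trimming.
#' Duplicate vial keys on either side are an error: pairing must be
#' unambiguous, never first-match.
#'
#' @param mones a [mone_matrix()].
#' @param expr an [expression_matrix()].
#' @return data.frame with columns `slide_row`, `expr_row`, `vial_id`, one
#'   row per matched pair, in slide order. Zero rows (with a warning) when
#'   the key sets are disjoint.
#' @export
match_slides_to_expression <- function(mones, expr) {
  stopifnot(inherits(mones, "mone_matrix"), inherits(expr, "expression_matrix"))
  sk <- toupper(trimws(mones$meta$vial_id))
  ek <- toupper(trimws(expr$vial_id))
  common <- intersect(sk, ek)
  dup_s <- unique(sk[duplicated(sk)])
  dup_e <- unique(ek[duplicated(ek)])
  amb <- union(intersect(dup_s, common), intersect(dup_e, common))
  if (length(amb))
    stop("ambiguous vial_id (present more than once): ",
         paste(amb, collapse = ", "))
  if (length(common) == 0) {
    warning("no shared vial_id between slides and expression profiles")
    return(data.frame(slide_row = integer(0), expr_row = integer(0),
                      vial_id = character(0), stringsAsFactors = FALSE))
  }
  s_idx <- which(sk %in% common)
  data.frame(slide_row = s_idx,
             expr_row = match(sk[s_idx], ek),
             vial_id = sk[s_idx],
             stringsAsFactors = FALSE)
}
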