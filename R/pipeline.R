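#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param simulate optional [generator_config()]; when given, the cohort is
#'   generated rather than read from files.
#' @param tiles,meta,expr input file paths (TSV/Feather) used when
#'   `simulate` is `NULL`; `expr` may be `NULL` to skip integration.
#' @param contrast metadata column defining the two classes for the
#'   differential and OBF stages (default `"lesion"`).
#' @param alpha named list of stage significance levels; defaults:
#'   differential 0.05, high_correlation 0.001, integration 0.05.
#' @param stages subset of
#'   `c("aggregate", "differential", "correlation", "classification",
#'   "integration")` to run.
#' @param seed integer seed for the stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, tiles = NULL,
                            meta = NULL, expr = NULL, contrast = "lesion",
                            alpha = list(), stages = c("aggregate",
                                                       "differential",
                                                       "correlation",
                                                       "classification",
                                                       "integration"),
                            seed = 1) {
  defaults <- list(differential = 0.05, high_correlation = 0.001,
                   integration = 0.05)
  alpha <- utils::modifyList(defaults, alpha)
  stopifnot(all(unlist(alpha) > 0), all(unlist(alpha) < 1))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(simulate)) {
    if (is.null(tiles) || is.null(meta))
      stop("either 'simulate' or both 'tiles' and 'meta' paths are required")
    for (p in c(tiles, meta, expr))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  if ("integration" %in% stages && is.null(simulate) && is.null(expr))
    stop("integration stage enabled but no expression input given")
  structure(list(out_dir = out_dir, simulate = simulate, tiles = tiles,
                 meta = meta, expr = expr, contrast = contrast,
                 alpha = alpha, stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full mone analysis pipeline
#'
#' Executes aggregate, differential (+OBF), correlation, classification and
#' integration in order on a simulated or file-based cohort, writing
#' per-stage tables under `out_dir` and a JSON manifest recording the seed,
#' the effective configuration and the row/feature counts of every output.
#' A failing stage aborts with the stage name after writing the partial
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "monekit",
                   version = as.character(utils::packageVersion("monekit")),
                   seed = config$seed, contrast = config$contrast,
                   alpha = config$alpha, outputs = list())
  t0 <- Sys.time()
  note <- function(stage, file, dims) {
    message(sprintf("[%s] %s (%s) %.1fs", stage, file,
                    paste(dims, collapse = " x "),
                    as.numeric(Sys.time() - t0, units = "secs")))
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    list(list(file = file, dims = dims)))
  }
  fail <- function(stage, e) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }

  # inputs
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    tiles <- cohort$tiles; meta <- cohort$meta
    expr <- if ("integration" %in% config$stages)
      generate_expression(cohort$truth, meta, config$simulate) else NULL
  } else {
    tiles <- read_tile_table(config$tiles)
    md <- read_table_any(config$meta)
    meta <- slide_meta(md$slide_id, md$patient_id, md$cancer_type, md$lesion,
                       md$preparation, md$vial_id)
    expr <- if (!is.null(config$expr)) read_expression_matrix(config$expr)
            else NULL
  }

  # aggregate
  mones <- tryCatch(aggregate_tiles(tiles, meta), error = function(e)
    fail("aggregate", e))
  if ("aggregate" %in% config$stages) {
    f <- file.path(config$out_dir, "mones.tsv")
    write_mone_matrix(mones, f, file.path(config$out_dir, "meta.tsv"))
    note("aggregate", "mones.tsv", dim(mones$values))
  }

  contrast_labels <- meta[[config$contrast]]

  if ("differential" %in% config$stages) {
    res <- tryCatch({
      dr <- run_tests(mones, contrast_labels)
      ob <- obf_scan(mones, contrast_labels)
      dr$obf_posterior <- ob$posterior
      dr$am <- ob$am
      dr$fdr_obf_selected <- FALSE
      sel <- select_fdr_obf(ob$posterior, config$alpha$differential)
      dr$fdr_obf_selected[sel$selected] <- TRUE
      dr
    }, error = function(e) fail("differential", e))
    f <- file.path(config$out_dir, "differential.tsv")
    write_table_any(as.data.frame(res), f)
    note("differential", "differential.tsv", dim(res))
  }

  if ("correlation" %in% config$stages) {
    res <- tryCatch({
      frozen <- which(meta$preparation == "frozen")
      sub <- if (length(frozen) >= 2) subset_mones(mones, frozen) else mones
      cr <- shrinkage_correlation(sub)
      cp <- correlated_pairs(cr, config$alpha$differential)
      list(r = cr$r, pairs = cp$pairs, fraction = cp$fraction_significant)
    }, error = function(e) fail("correlation", e))
    f <- file.path(config$out_dir, "correlated_pairs.tsv")
    write_table_any(res$pairs, f)
    note("correlation", "correlated_pairs.tsv",
         c(nrow(res$pairs), ncol(res$pairs)))
  }

  if ("classification" %in% config$stages) {
    res <- tryCatch({
      cls <- paste(meta$cancer_type, contrast_labels, sep = "_")
      monte_carlo_cv(mones, cls, model = "lasso", n_reps = 3,
                     test_fraction = 0.25, seed = config$seed)
    }, error = function(e) fail("classification", e))
    f <- file.path(config$out_dir, "classification_auc.tsv")
    write_table_any(as.data.frame(res$auc), f)
    note("classification", "classification_auc.tsv", dim(res$auc))
  }

  if ("integration" %in% config$stages) {
    res <- tryCatch({
      if (is.null(expr)) stop("no expression data available")
      pairs <- match_slides_to_expression(mones, expr)
      sub <- expression_matrix(expr$values[pairs$expr_row, , drop = FALSE],
                               expr$vial_id[pairs$expr_row])
      kept <- filter_genes(sub)
      mone_gene_correlation(mones, kept, config$alpha$integration,
                            pairs = data.frame(slide_row = pairs$slide_row,
                                               expr_row = seq_len(nrow(pairs))))
    }, error = function(e) fail("integration", e))
    f <- file.path(config$out_dir, "mone_gene_pairs.tsv")
    write_table_any(res$pairs_significant, f)
    note("integration", "mone_gene_pairs.tsv",
         c(nrow(res$pairs_significant), ncol(res$pairs_significant)))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
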