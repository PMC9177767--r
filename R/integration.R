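#' Gene filters for integrative analysis
#'
#' @param max_zero_fraction drop genes with zero expression in more than
#'   this fraction of the paired samples ("zero counts" are taken as exact
#'   zeros of the log-normalized matrix, the pre-log zeros).
#' @param min_sd drop genes whose expression standard deviation over the
#'   paired samples is below this value.
#' @return list of class `gene_filter_config`.
#' @export
gene_filter_config <- function(max_zero_fraction = 0.5, min_sd = 0.25) {
  stopifnot(max_zero_fraction >= 0, max_zero_fraction <= 1, min_sd >= 0)
  structure(list(max_zero_fraction = max_zero_fraction, min_sd = min_sd),
            class = "gene_filter_config")
}

#' Filter genes before mone-gene correlation
#'
#' Removes genes with too many zeros or too little variation across the
#' paired samples; gene order is preserved. Idempotent: filtering an
#' already-filtered matrix changes nothing.
#'
#' @param expr an [expression_matrix()] restricted to the paired samples.
#' @param config a [gene_filter_config()].
#' @return the filtered [expression_matrix()]; the dropped gene names are
#'   attached as attribute `dropped`.
#' @export
filter_genes <- function(expr, config = gene_filter_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  zero_frac <- colMeans(v == 0)
  sds <- apply(v, 2L, stats::sd)
  keep <- zero_frac <= config$max_zero_fraction & sds >= config$min_sd
  if (!any(keep)) stop("all genes removed by the expression filters")
  out <- expression_matrix(v[, keep, drop = FALSE], expr$vial_id,
                           colnames(v)[keep])
  attr(out, "dropped") <- colnames(v)[!keep]
  out
}

#' Mone-gene correlation block
#'
#' Stacks the paired slide-level mones and gene expression values into one
#' matrix, estimates its Ledoit-Wolf shrunk covariance, converts to
#' correlations, and tests the mone x gene block (only) with Fisher tests
#' and BH adjustment over that block. As in [correlated_pairs()], the test
#' statistic uses the sample correlations (for which the Fisher z null is
#' calibrated) while the shrunk block is the reported estimate.
#'
#' @param mones a [mone_matrix()].
#' @param expr a filtered [expression_matrix()].
#' @param alpha FDR level.
#' @param pairs optional pairing from [match_slides_to_expression()];
#'   computed when `NULL`.
#' @param use_shrinkage test the shrunk rather than the sample
#'   coefficients.
#' @return list with `r` (shrunk mones x genes), `r_sample`, `p`, `q`,
#'   `n_effective`, `shrinkage`, and `pairs_significant` (data.frame
#'   `mone`, `gene`, `r`, `p`, `q`).
#' @export
mone_gene_correlation <- function(mones, expr, alpha = 0.05, pairs = NULL,
                                  use_shrinkage = FALSE) {
  if (is.null(pairs)) pairs <- match_slides_to_expression(mones, expr)
  if (nrow(pairs) < 4) stop("need at least 4 paired samples")
  xm <- mones$values[pairs$slide_row, , drop = FALSE]
  xg <- expr$values[pairs$expr_row, , drop = FALSE]
  M <- ncol(xm); G <- ncol(xg)
  lw <- ledoit_wolf(cbind(xm, xg))
  sdv <- sqrt(pmax(diag(lw$cov), .Machine$double.eps))
  r_full <- lw$cov / tcrossprod(sdv)
  r <- r_full[seq_len(M), M + seq_len(G), drop = FALSE]
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(colnames(xm), colnames(xg))
  r_sample <- suppressWarnings(stats::cor(xm, xg))
  r_sample[!is.finite(r_sample)] <- 0
  n <- nrow(xm)
  r_test <- if (use_shrinkage) r else r_sample
  p <- matrix(fisher_test(as.numeric(r_test), n), M, G,
              dimnames = dimnames(r))
  q <- matrix(stats::p.adjust(as.numeric(p), method = "BH"), M, G,
              dimnames = dimnames(r))
  sig <- which(q <= alpha, arr.ind = TRUE)
  sig_df <- data.frame(mone = rownames(r)[sig[, 1]],
                       gene = colnames(r)[sig[, 2]],
                       r = r_test[sig], p = p[sig], q = q[sig],
                       stringsAsFactors = FALSE)
  list(r = r, r_sample = r_sample, p = p, q = q, n_effective = n,
       shrinkage = lw$shrinkage, pairs_significant = sig_df)
}

#' Extract correlated mone-gene biclusters
#'
#' Builds the bipartite graph with an edge wherever the adjusted p-value is
#' at most `alpha` and returns its connected components that contain at
#' least 2 mones and 2 genes.
#'
#' @param block a [mone_gene_correlation()] result (or any list with `r`
#'   and `q` mone x gene matrices).
#' @param alpha FDR level for an edge.
#' @param min_mones,min_genes component size thresholds.
#' @return list of components, each with `mones`, `genes`, `mean_abs_r`,
#'   and `n_edges`.
#' @export
extract_bicluster <- function(block, alpha = 0.05, min_mones = 2,
                              min_genes = 2) {
  q <- block$q; r <- block$r
  edges <- which(q <= alpha, arr.ind = TRUE)
  if (nrow(edges) == 0) return(list())
  mn <- paste0("m:", rownames(q)[edges[, 1]])
  gn <- paste0("g:", colnames(q)[edges[, 2]])
  g <- igraph::graph_from_edgelist(cbind(mn, gn), directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    verts <- names(comp$membership)[comp$membership == k]
    mones_k <- sub("^m:", "", verts[startsWith(verts, "m:")])
    genes_k <- sub("^g:", "", verts[startsWith(verts, "g:")])
    if (length(mones_k) < min_mones || length(genes_k) < min_genes) next
    in_comp <- rownames(q)[edges[, 1]] %in% mones_k &
      colnames(q)[edges[, 2]] %in% genes_k
    rr <- r[edges[in_comp, , drop = FALSE]]
    out[[length(out) + 1]] <- list(mones = mones_k, genes = genes_k,
                                   mean_abs_r = mean(abs(rr)),
                                   n_edges = sum(in_comp))
  }
  out
}

#' First principal component of a mone cluster
#'
#' PCA on the member columns (centered, not scaled: members of a correlated
#' cluster live on the same feature scale family). The PC-1 sign is fixed
#' so the loading of the member with the smallest id is non-negative.
#'
#' @param mones a [mone_matrix()] or matrix restricted to the member
#'   features.
#' @param members optional feature ids selecting columns.
#' @return list of class `cluster_score`: `members`, `loadings`
#'   (unit norm), `scores` (per-sample PC-1), `variance_explained`.
#' @export
cluster_pc1 <- function(mones, members = NULL) {
  x <- if (inherits(mones, "mone_matrix")) mones$values else as.matrix(mones)
  if (!is.null(members)) x <- x[, as.character(members), drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 member mones")
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (all(apply(x, 2L, stats::var) == 0)) stop("degenerate member set")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, 1]
  ids <- suppressWarnings(as.numeric(colnames(x)))
  first <- if (all(is.finite(ids))) which.min(ids) else 1L
  if (load[first] < 0) load <- -load
  scores <- as.numeric(scale(x, center = TRUE, scale = FALSE) %*% load)
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  structure(list(members = colnames(x), loadings = load, scores = scores,
                 variance_explained = ve), class = "cluster_score")
}

#' Correlate a per-sample score with an external covariate
#'
#' Pairwise-complete Pearson correlation with a Fisher-transform p-value.
#' An optional trim rule removes samples whose covariate exceeds a stated
#' threshold before correlating (e.g. the B-cell fraction outlier rule);
#' fraction-valued covariates are expected to be log-normalized upstream.
#'
#' @param score numeric per-sample values.
#' @param covariate numeric per-sample covariate (same length; `NA`s
#'   allowed and dropped pairwise).
#' @param trim_above optional threshold; samples with covariate strictly
#'   above it are dropped. Applied on the scale of `trim_on` (the raw
#'   covariate by default).
#' @param trim_on optional vector the trim threshold refers to (e.g. raw
#'   fractions when `covariate` is log-normalized); defaults to `covariate`.
#' @return list with `r`, `p`, `n` (pairs used), and `trimmed` (indices
#'   removed).
#' @export
correlate_with_covariate <- function(score, covariate, trim_above = NULL,
                                     trim_on = NULL) {
  stopifnot(length(score) == length(covariate))
  if (is.null(trim_on)) trim_on <- covariate
  trimmed <- integer(0)
  if (!is.null(trim_above)) {
    trimmed <- which(!is.na(trim_on) & trim_on > trim_above)
    if (length(trimmed)) {
      score <- score[-trimmed]; covariate <- covariate[-trimmed]
    }
  }
  ok <- stats::complete.cases(score, covariate)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 complete pairs")
  r <- stats::cor(score[ok], covariate[ok])
  list(r = r, p = as.numeric(fisher_test(r, n)), n = n, trimmed = trimmed)
}

#' Immunoglobulin-set score
#'
#' Per-sample arithmetic mean of the log-normalized expression of a gene
#' set. By default every member gene must be present; a lower
#' `min_coverage` allows scoring from the present subset, with the missing
#' genes reported.
#'
#' @param expr an [expression_matrix()].
#' @param gene_set character vector of gene symbols.
#' @param min_coverage minimum fraction of the set that must be present.
#' @return numeric per-sample score; missing genes attached as attribute
#'   `missing_genes`.
#' @export
ig_score <- function(expr, gene_set, min_coverage = 1) {
  stopifnot(inherits(expr, "expression_matrix"), length(gene_set) >= 1)
  present <- intersect(gene_set, colnames(expr$values))
  if (length(present) == 0) stop("no member gene present in the matrix")
  coverage <- length(present) / length(gene_set)
  if (coverage < min_coverage)
    stop(sprintf("gene-set coverage %.2f below required %.2f; missing: %s",
                 coverage, min_coverage,
                 paste(setdiff(gene_set, present), collapse = ", ")))
  out <- rowMeans(expr$values[, present, drop = FALSE])
  attr(out, "missing_genes") <- setdiff(gene_set, present)
  out
}
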