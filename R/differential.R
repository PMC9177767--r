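#' Frequentist differential mone analysis
#'
#' Runs per-feature two-class tests -- Welch's unequal-variance t test,
#' the two-sample Kolmogorov-Smirnov test, and the Wilcoxon rank-sum test --
#' and applies Benjamini-Hochberg adjustment within each test family across
#' all features. The rank-sum test is computed exactly (network algorithm)
#' when both classes have fewer than 20 slides and there are no ties, and by
#' the tie- and continuity-corrected normal approximation otherwise.
#'
#' A feature that is constant across both classes carries no information:
#' its p-values are set to 1 and it is flagged in the `degenerate` column
#' rather than propagating `NaN`.
#'
#' @param mones a [mone_matrix()] or plain numeric matrix (slides x features).
#' @param labels binary class labels, one per slide (0/1, logical, or a
#'   2-level factor); class 1 is the second sorted level.
#' @param tests subset of `c("t", "ks", "wrs")`.
#' @return data.frame of class `differential_result`, one row per feature:
#'   group sizes `n0`, `n1`, `direction` (sign of class-1 mean minus class-0
#'   mean), and for each requested test its statistic, raw p, and BH-adjusted
#'   q, plus a logical `degenerate` flag.
#' @export
run_tests <- function(mones, labels, tests = c("t", "ks", "wrs")) {
  tests <- match.arg(tests, several.ok = TRUE)
  x <- if (inherits(mones, "mone_matrix")) mones$values else as.matrix(mones)
  if (is.null(colnames(x)))
    colnames(x) <- as.character(seq_len(ncol(x)) - 1L)
  lab <- as_binary_labels(labels, nrow(x))
  x0 <- x[lab == 0L, , drop = FALSE]
  x1 <- x[lab == 1L, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  if (n0 < 2 || n1 < 2)
    stop("each class needs at least 2 slides (got ", n0, " and ", n1, ")")
  M <- ncol(x)
  out <- data.frame(feature = colnames(x), n0 = n0, n1 = n1,
                    direction = sign(colMeans(x1) - colMeans(x0)),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (tt in tests) {
    st <- rep(NA_real_, M); pv <- rep(NA_real_, M)
    for (j in seq_len(M)) {
      a <- x0[, j]; b <- x1[, j]
      const <- stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)
      if (const) {
        out$degenerate[j] <- TRUE
        st[j] <- 0; pv[j] <- 1
        next
      }
      if (tt == "t") {
        if (stats::var(a) == 0 && stats::var(b) == 0) {
          # equal constants handled above; distinct constants separate fully
          st[j] <- Inf * sign(mean(b) - mean(a)); pv[j] <- 0
        } else {
          r <- stats::t.test(b, a, var.equal = FALSE)
          st[j] <- unname(r$statistic); pv[j] <- r$p.value
        }
      } else if (tt == "ks") {
        r <- suppressWarnings(stats::ks.test(a, b))
        st[j] <- unname(r$statistic); pv[j] <- r$p.value
      } else {
        exact <- (n0 < 20 && n1 < 20)
        r <- suppressWarnings(stats::wilcox.test(b, a, exact = exact,
                                                 correct = TRUE))
        st[j] <- unname(r$statistic); pv[j] <- r$p.value
      }
    }
    out[[paste0("stat_", tt)]] <- st
    out[[paste0("p_", tt)]] <- pv
    out[[paste0("q_", tt)]] <- stats::p.adjust(pv, method = "BH")
  }
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Agreement between significant-feature sets
#'
#' Given the significant sets reported by several tests over the same
#' feature universe, returns the exact counts of every region of the Venn
#' diagram and the consensus ratio |intersection| / |union|.
#'
#' @param sets named list of vectors of significant feature ids.
#' @return list with `regions` (data.frame of membership pattern counts),
#'   `n_intersection`, `n_union`, and `ratio` (`NA` when the union is empty).
#' @export
consensus_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  if (length(universe) == 0) {
    return(list(regions = data.frame(), n_intersection = 0L, n_union = 0L,
                ratio = NA_real_))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k, dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(z) paste(as.integer(z), collapse = ""))
  counts <- table(pattern)
  regions <- data.frame(pattern = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  n_int <- sum(rowSums(member) == k)
  list(regions = regions, n_intersection = n_int,
       n_union = length(universe), ratio = n_int / length(universe))
}

#' Top-k features by differential significance
#'
#' Features are ranked by raw p-value (ascending) for the chosen test; ties
#' are broken by larger absolute statistic, then by feature id.
#'
#' @param result a [run_tests()] result.
#' @param k number of features to return (1..M).
#' @param by which test's p-values to rank by.
#' @return character vector of the top `k` feature ids in rank order.
#' @export
top_k_markers <- function(result, k, by = c("t", "ks", "wrs")) {
  by <- match.arg(by)
  pcol <- paste0("p_", by); scol <- paste0("stat_", by)
  if (!pcol %in% names(result)) stop("test '", by, "' was not run")
  if (k <= 0) stop("k must be positive")
  if (k > nrow(result)) stop("k exceeds the number of features")
  ord <- order(result[[pcol]], -abs(result[[scol]]), result$feature)
  result$feature[ord][seq_len(k)]
}
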