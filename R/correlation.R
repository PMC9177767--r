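#' Ledoit-Wolf shrinkage covariance
#'
#' The Ledoit-Wolf estimator blends the (biased, 1/n) sample covariance S
#' with the scaled identity target mu*I, mu = tr(S)/p, using the
#' analytically optimal shrinkage intensity estimated from the data. This is
#' the standard well-conditioned estimator for p comparable to or larger
#' than n.
#'
#' @param x numeric matrix, observations x variables.
#' @param shrinkage optional shrinkage intensity in \[0, 1\] to force
#'   (0 gives the plain sample covariance); estimated when `NULL`.
#' @return list with `cov` (p x p shrunk covariance), `shrinkage`, and `mu`.
#' @export
ledoit_wolf <- function(x, shrinkage = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("Ledoit-Wolf needs at least 2 observations")
  xc <- sweep(x, 2L, colMeans(x))
  S <- crossprod(xc) / n
  mu <- sum(diag(S)) / p
  if (is.null(shrinkage)) {
    delta <- sum(S^2) / p - 2 * mu * sum(diag(S)) / p + mu^2
    if (delta == 0) {
      shrinkage <- 0
    } else {
      x2 <- xc^2
      beta <- (sum(crossprod(x2)) / n - sum(crossprod(xc)^2) / n^2) / (n * p)
      shrinkage <- min(beta, delta) / delta
    }
  }
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  cov <- (1 - shrinkage) * S
  diag(cov) <- diag(cov) + shrinkage * mu
  list(cov = cov, shrinkage = shrinkage, mu = mu)
}

#' Shrinkage correlation matrix of a mone matrix
#'
#' Computes the Ledoit-Wolf shrunk covariance of the slides-by-features
#' matrix and normalizes it to a correlation matrix. Constant features are
#' flagged and their correlations reported as 0 rather than `NaN`.
#'
#' @param mones a [mone_matrix()] or numeric matrix (slides x features).
#' @param shrinkage optional forced shrinkage intensity (see [ledoit_wolf()]).
#' @return object of class `correlation_result`: list with `r` (shrunk,
#'   symmetric, unit diagonal), `r_sample` (plain sample correlations, used
#'   by the significance tests), `n_effective` (raw slide count),
#'   `shrinkage`, and `degenerate` (logical per feature).
#' @export
shrinkage_correlation <- function(mones, shrinkage = NULL) {
  x <- if (inherits(mones, "mone_matrix")) mones$values else as.matrix(mones)
  if (nrow(x) < 2) stop("need at least 2 slides")
  lw <- ledoit_wolf(x, shrinkage = shrinkage)
  d <- diag(lw$cov)
  degenerate <- apply(x, 2L, function(col) stats::var(col) == 0)
  sdv <- sqrt(pmax(d, 0))
  sdv[sdv == 0] <- 1  # avoid 0/0; degenerate rows zeroed below
  r <- lw$cov / tcrossprod(sdv)
  rs <- suppressWarnings(stats::cor(x))
  rs[!is.finite(rs)] <- 0
  r[degenerate, ] <- 0; r[, degenerate] <- 0
  rs[degenerate, ] <- 0; rs[, degenerate] <- 0
  diag(r) <- 1; diag(rs) <- 1
  r <- pmin(pmax(r, -1), 1)
  rs <- pmin(pmax(rs, -1), 1)
  dimnames(r) <- dimnames(rs) <- list(colnames(x), colnames(x))
  structure(list(r = r, r_sample = rs, n_effective = nrow(x),
                 shrinkage = lw$shrinkage, degenerate = degenerate),
            class = "correlation_result")
}

#' Fisher-transform correlation test
#'
#' Tests a correlation coefficient against a point null `rho = null_rho`
#' (or, for `null_rho > 0`, the composite null `|rho| <= null_rho` evaluated
#' at the boundary with the sign of r): the statistic
#' `(atanh(r) - sign(r) atanh(null_rho)) * sqrt(n - 3)` is referred to the
#' standard normal.
#'
#' @param r correlation coefficient(s), vectorized.
#' @param n sample size (scalar or vector, >= 4).
#' @param null_rho null correlation magnitude in \[0, 1).
#' @param sided `"two"`, `"greater"`, or `"less"`.
#' @return numeric p-value(s); an `exact` attribute flags entries where
#'   `|r| = 1` (p reported as 0).
#' @export
fisher_test <- function(r, n, null_rho = 0, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (any(n < 4)) stop("Fisher test needs n >= 4")
  stopifnot(null_rho >= 0, null_rho < 1, all(abs(r) <= 1))
  exact <- abs(r) == 1
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  z0 <- if (null_rho == 0) 0 else sign(r) * atanh(null_rho)
  stat <- (z - z0) * sqrt(n - 3)
  p <- switch(sided,
              two = 2 * stats::pnorm(-abs(stat)),
              greater = stats::pnorm(stat, lower.tail = FALSE),
              less = stats::pnorm(stat))
  p[exact] <- 0
  attr(p, "exact") <- exact
  p
}

#' Significant correlated pairs
#'
#' Applies the Fisher test to every upper-triangle pair of a correlation
#' matrix and Benjamini-Hochberg adjustment over that family. The test
#' statistic uses the plain sample correlations: the Fisher z null
#' distribution is calibrated for the sample estimator, whereas shrunk
#' coefficients are biased toward zero by a data-dependent amount (large
#' when most feature pairs are uncorrelated) and testing them at the same
#' nominal variance would be arbitrarily conservative. The shrunk matrix
#' remains the reported point estimate; set `use_shrinkage = TRUE` to test
#' the shrunk coefficients instead.
#'
#' @param result a [shrinkage_correlation()] result.
#' @param alpha FDR level.
#' @param null_rho null correlation magnitude (0 for the usual test; e.g.
#'   0.5 for the "highly correlated" analysis).
#' @param sided sidedness passed to [fisher_test()].
#' @param use_shrinkage test the shrunk coefficients rather than the sample
#'   coefficients.
#' @return list with `pairs` (data.frame `i`, `j`, `r`, `p`, `q` of the
#'   significant pairs), `fraction_significant`, and the full upper-triangle
#'   `p` and `q` matrices stored back on the result (`$p`, `$q`).
#' @export
correlated_pairs <- function(result, alpha, null_rho = 0, sided = "two",
                             use_shrinkage = FALSE) {
  stopifnot(inherits(result, "correlation_result"))
  r <- if (use_shrinkage || is.null(result$r_sample)) result$r
       else result$r_sample
  M <- ncol(r)
  ut <- which(upper.tri(r))
  pv <- fisher_test(r[ut], result$n_effective, null_rho = null_rho,
                    sided = sided)
  qv <- stats::p.adjust(as.numeric(pv), method = "BH")
  pm <- qm <- matrix(NA_real_, M, M, dimnames = dimnames(r))
  pm[ut] <- pv; qm[ut] <- qv
  sig <- ut[qv <= alpha]
  ij <- arrayInd(sig, dim(r))
  lbl <- colnames(r)
  pairs <- data.frame(
    i = if (is.null(lbl)) ij[, 1] else lbl[ij[, 1]],
    j = if (is.null(lbl)) ij[, 2] else lbl[ij[, 2]],
    r = r[sig], p = pm[sig], q = qm[sig], stringsAsFactors = FALSE)
  result$p <- pm; result$q <- qm
  list(pairs = pairs, fraction_significant = length(sig) / length(ut),
       result = result)
}

#' Pooled correlation matrix
#'
#' Element-wise arithmetic mean of correlation matrices from several
#' cohorts, with the diagonal re-set to exactly 1.
#'
#' @param matrices list of same-shaped correlation matrices.
#' @return pooled matrix.
#' @export
pooled_correlation <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("correlation matrices have mismatched shapes")
  out <- Reduce(`+`, matrices) / length(matrices)
  diag(out) <- 1
  out
}

# canonical unordered pair keys from a pairs data.frame
pair_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  a <- pmin(as.character(pairs$i), as.character(pairs$j))
  b <- pmax(as.character(pairs$i), as.character(pairs$j))
  paste(a, b, sep = "|")
}

#' Cross-cancer preservation of correlated pairs
#'
#' Among feature pairs significantly correlated in at least one cancer of a
#' family, the fraction significant in every cancer of the family.
#'
#' @param per_cancer_pairs named list; each element either a character
#'   vector of canonical pair keys or a data.frame with columns `i`, `j`.
#' @return list with `fraction` (`NA` when the union is empty),
#'   `n_intersection`, `n_union`.
#' @export
family_preservation <- function(per_cancer_pairs) {
  keysets <- lapply(per_cancer_pairs, function(p) {
    if (is.data.frame(p)) pair_keys(p) else as.character(p)
  })
  uni <- unique(unlist(keysets, use.names = FALSE))
  if (length(uni) == 0)
    return(list(fraction = NA_real_, n_intersection = 0L, n_union = 0L))
  inter <- Reduce(intersect, keysets)
  list(fraction = length(inter) / length(uni),
       n_intersection = length(inter), n_union = length(uni))
}

#' Differential correlation between tumor and normal slides
#'
#' Computes the tumor-minus-normal difference of correlation matrices and
#' tests each pair with the two-sample Fisher statistic
#' `(z_t - z_n) / sqrt(1/(n_t - 3) + 1/(n_n - 3))` against the standard
#' normal, with BH adjustment over the upper triangle.
#'
#' @param tumor,normal mone matrices (or plain matrices) over the same
#'   features; each needs >= 4 slides.
#' @param alpha FDR level.
#' @param use_shrinkage difference the Ledoit-Wolf correlations instead of
#'   the plain sample correlations. Default `FALSE`: the two groups get
#'   different data-driven shrinkage intensities, which would bias the
#'   difference, and the Fisher null is calibrated for sample coefficients.
#' @return list with `delta_r`, `stat`, `p`, `q` matrices (upper triangle),
#'   the significant `pairs` data.frame, and group sizes.
#' @export
differential_correlation <- function(tumor, normal, alpha = 0.05,
                                     use_shrinkage = FALSE) {
  xt <- if (inherits(tumor, "mone_matrix")) tumor$values else as.matrix(tumor)
  xn <- if (inherits(normal, "mone_matrix")) normal$values else as.matrix(normal)
  if (nrow(xt) < 4 || nrow(xn) < 4)
    stop("each group needs at least 4 slides")
  if (ncol(xt) != ncol(xn)) stop("feature spaces differ")
  shr <- if (use_shrinkage) NULL else 0
  rt <- shrinkage_correlation(xt, shrinkage = shr)$r
  rn <- shrinkage_correlation(xn, shrinkage = shr)$r
  nt <- nrow(xt); nn <- nrow(xn)
  clamp <- function(r) pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  stat <- (atanh(clamp(rt)) - atanh(clamp(rn))) /
    sqrt(1 / (nt - 3) + 1 / (nn - 3))
  delta <- rt - rn
  M <- ncol(rt)
  ut <- which(upper.tri(delta))
  pv <- 2 * stats::pnorm(-abs(stat[ut]))
  qv <- stats::p.adjust(pv, method = "BH")
  pm <- qm <- matrix(NA_real_, M, M, dimnames = dimnames(delta))
  pm[ut] <- pv; qm[ut] <- qv
  sig <- ut[qv <= alpha]
  ij <- arrayInd(sig, dim(delta))
  lbl <- colnames(delta)
  pairs <- data.frame(
    i = if (is.null(lbl)) ij[, 1] else lbl[ij[, 1]],
    j = if (is.null(lbl)) ij[, 2] else lbl[ij[, 2]],
    delta_r = delta[sig], p = pm[sig], q = qm[sig], stringsAsFactors = FALSE)
  list(delta_r = delta, stat = stat, p = pm, q = qm, pairs = pairs,
       n_tumor = nt, n_normal = nn)
}
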