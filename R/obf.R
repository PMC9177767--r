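#' Optimal Bayesian Filter configuration
#'
#' The OBF scores each feature by the posterior probability that its
#' class-conditional distributions differ ("marker") rather than coincide
#' ("non-marker"). Data in each homogeneous block are modeled as Gaussian
#' with unknown mean and variance under the improper Jeffreys scale prior
#' \eqn{(\sigma^2)^{-3/2}}; each block's prior carries normalization
#' \eqn{c / \sqrt{n_S}} (the flat location prior normalized at the block's
#' effective information scale), so the marginal likelihood of a block of
#' \eqn{n} observations with centered sum of squares \eqn{SS} is
#' \deqn{m(S) = c \, (2\pi)^{-(n-1)/2} \, n^{-1} \, \Gamma(n/2) \, (SS/2)^{-n/2}.}
#' With \eqn{c = 0.1} and marker prior 0.5 this normalization reproduces the
#' published effect-size thresholds a(m) = 1.088 (balanced total n = 200)
#' and 1.159 (total n = 100) at posterior 0.95.
#'
#' @param prior_marker prior probability that a feature is a marker.
#' @param norm_const normalization constant of the improper prior, one
#'   factor per Gaussian block.
#' @param alpha FDR level used by the selection rules.
#' @return list of class `obf_config`.
#' @export
obf_config <- function(prior_marker = 0.5, norm_const = 0.1, alpha = 0.05) {
  stopifnot(prior_marker > 0, prior_marker < 1, norm_const > 0,
            alpha > 0, alpha < 1)
  structure(list(prior_marker = prior_marker, norm_const = norm_const,
                 alpha = alpha), class = "obf_config")
}

#' Log marginal likelihood of one Gaussian block
#'
#' Closed form for the marginal of a block of observations under the OBF
#' model (see [obf_config()]). Either raw data `x` or the sufficient
#' statistics `n` and `ss` (centered sum of squares) may be supplied.
#'
#' @param x numeric vector of observations (length >= 2), or `NULL` when
#'   sufficient statistics are given.
#' @param config an [obf_config()].
#' @param n,ss sufficient statistics, used when `x` is `NULL`.
#' @return log marginal likelihood (scalar).
#' @export
block_log_marginal <- function(x = NULL, config = obf_config(), n = NULL,
                               ss = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2) stop("a block needs at least 2 observations")
    if (!all(is.finite(x))) stop("non-finite observation in block")
    n <- length(x)
    ss <- sum((x - mean(x))^2)
  }
  if (is.null(n) || is.null(ss)) stop("supply either x or both n and ss")
  if (n < 2) stop("a block needs at least 2 observations")
  if (ss <= 0)
    stop("degenerate block: zero sum of squared deviations (constant data)")
  log(config$norm_const) - (n - 1) / 2 * log(2 * pi) - log(n) +
    lgamma(n / 2) - (n / 2) * log(ss / 2)
}

#' The a(m) effect-size statistic
#'
#' Ratio of the total (pooled) sample variance to the degrees-of-freedom
#' weighted geometric mean of the class-conditional sample variances,
#' \deqn{a(m) = s^2 / (s_0^{2 w_0} s_1^{2 w_1}), \quad
#'       w_y = (n_y - 1)/(n_0 + n_1 - 2),}
#' using unbiased variances. It tends to 1 for non-markers and grows with
#' distributional differences between the classes.
#'
#' @param x0,x1 numeric vectors of the two classes (each length >= 2).
#' @return a(m) (scalar, > 0).
#' @export
am_statistic <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  stopifnot(n0 >= 2, n1 >= 2)
  s2 <- stats::var(c(x0, x1))
  s20 <- stats::var(x0); s21 <- stats::var(x1)
  if (s20 <= 0 || s21 <= 0 || s2 <= 0) stop("degenerate variance in a(m)")
  w0 <- (n0 - 1) / (n0 + n1 - 2)
  w1 <- (n1 - 1) / (n0 + n1 - 2)
  exp(log(s2) - w0 * log(s20) - w1 * log(s21))
}

marker_posterior_stats <- function(n0, ss0, n1, ss1, ss_tot, config) {
  lm0 <- block_log_marginal(config = config, n = n0 + n1, ss = ss_tot)
  lm1 <- block_log_marginal(config = config, n = n0, ss = ss0) +
    block_log_marginal(config = config, n = n1, ss = ss1)
  lpost <- log(config$prior_marker) + lm1
  lnull <- log(1 - config$prior_marker) + lm0
  mx <- max(lpost, lnull)
  post <- exp(lpost - mx) / (exp(lpost - mx) + exp(lnull - mx))
  list(posterior = post, log_m0 = lm0, log_m1 = lm1)
}

#' Two-class OBF marker posterior
#'
#' Posterior probability that a feature's distribution differs between two
#' classes. The non-marker marginal pools both classes into one Gaussian
#' block; the marker marginal is the product of per-class block marginals
#' (one prior normalization factor per block). Computation is in the log
#' domain throughout.
#'
#' @param x0,x1 numeric class samples (each length >= 2, non-constant).
#' @param config an [obf_config()].
#' @return list with `posterior`, `am`, `log_m0`, `log_m1`.
#' @export
marker_posterior <- function(x0, x1, config = obf_config()) {
  if (length(x0) < 2) stop("class 0 block needs at least 2 observations")
  if (length(x1) < 2) stop("class 1 block needs at least 2 observations")
  ss0 <- sum((x0 - mean(x0))^2)
  ss1 <- sum((x1 - mean(x1))^2)
  xa <- c(x0, x1)
  sst <- sum((xa - mean(xa))^2)
  if (ss0 <= 0) stop("degenerate variance in block 'class0'")
  if (ss1 <= 0) stop("degenerate variance in block 'class1'")
  if (sst <= 0) stop("degenerate variance in block 'pooled'")
  res <- marker_posterior_stats(length(x0), ss0, length(x1), ss1, sst, config)
  res$am <- am_statistic(x0, x1)
  res
}

#' OBF posteriors for every feature of a mone matrix
#'
#' @param mones a [mone_matrix()] (or plain numeric matrix).
#' @param labels binary vector (0/1, logical, or 2-level factor) per slide.
#' @param config an [obf_config()].
#' @return data.frame with one row per feature: `feature`, `posterior`,
#'   `am`, `log_m0`, `log_m1`.
#' @export
obf_scan <- function(mones, labels, config = obf_config()) {
  x <- if (inherits(mones, "mone_matrix")) mones$values else as.matrix(mones)
  if (is.null(colnames(x)))
    colnames(x) <- as.character(seq_len(ncol(x)) - 1L)
  lab <- as_binary_labels(labels, nrow(x))
  x0 <- x[lab == 0L, , drop = FALSE]
  x1 <- x[lab == 1L, , drop = FALSE]
  if (nrow(x0) < 2 || nrow(x1) < 2) stop("each class needs at least 2 slides")
  out <- data.frame(feature = colnames(x), posterior = NA_real_,
                    am = NA_real_, log_m0 = NA_real_, log_m1 = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x))) {
    r <- marker_posterior(x0[, j], x1[, j], config)
    out$posterior[j] <- r$posterior
    out$am[j] <- r$am
    out$log_m0[j] <- r$log_m0
    out$log_m1[j] <- r$log_m1
  }
  out
}

#' Effect-size threshold on the a(m) scale
#'
#' Solves for the a(m) value at which the two-class marker posterior equals
#' `target_posterior`, in the reference configuration where the total sample
#' variance is held at `total_variance` and the two class-conditional
#' variances are equal (so the between-class mean shift carries the whole
#' effect). A bracketing root-finder is polished to
#' `|posterior - target| < 1e-10`.
#'
#' @param n0,n1 class sample sizes (each >= 2).
#' @param target_posterior posterior probability in (prior, 1).
#' @param config an [obf_config()].
#' @param total_variance total sample variance held fixed (default 1,
#'   i.e. standardized features).
#' @return the a(m) threshold (scalar > 1).
#' @export
am_threshold <- function(n0, n1, target_posterior, config = obf_config(),
                         total_variance = 1) {
  stopifnot(n0 >= 2, n1 >= 2, target_posterior > 0, target_posterior < 1)
  n <- n0 + n1
  post_at <- function(a) {
    v <- total_variance / a
    marker_posterior_stats(n0, (n0 - 1) * v, n1, (n1 - 1) * v,
                           (n - 1) * total_variance, config)$posterior
  }
  lo <- 1 + 1e-12; hi <- 100
  plo <- post_at(lo); phi <- post_at(hi)
  if ((plo - target_posterior) * (phi - target_posterior) > 0)
    stop(sprintf(paste0("target posterior %.4g not attainable for a(m) in ",
                        "[1, 100]: posterior ranges over [%.4g, %.4g]"),
                 target_posterior, min(plo, phi), max(plo, phi)))
  r <- stats::uniroot(function(a) post_at(a) - target_posterior, c(lo, hi),
                      tol = .Machine$double.eps^0.75)$root
  # polish by bisection until the posterior itself is within 1e-10
  lo2 <- r * (1 - 1e-6); hi2 <- r * (1 + 1e-6)
  for (i in 1:200) {
    mid <- (lo2 + hi2) / 2
    pm <- post_at(mid)
    if (abs(pm - target_posterior) < 1e-10) return(mid)
    inc <- post_at(hi2) > post_at(lo2)
    if ((pm < target_posterior) == inc) lo2 <- mid else hi2 <- mid
  }
  mid
}

#' Minimal-risk OBF selection
#'
#' Selects the features whose marker posterior exceeds `1 - alpha`.
#'
#' @param posteriors numeric vector in \[0, 1\].
#' @param alpha error level.
#' @return integer indices of the selected features.
#' @export
select_minimal_risk <- function(posteriors, alpha) {
  stopifnot(all(posteriors >= 0 & posteriors <= 1))
  which(posteriors > 1 - alpha)
}

#' FDR-OBF selection
#'
#' Sorts posteriors in decreasing order and returns the largest prefix whose
#' mean posterior error probability `mean(1 - p)` is at most `alpha` -- the
#' feature set whose sample-conditioned expected false discovery proportion
#' is bounded by `alpha`. Because `1 - p` is nondecreasing along the sorted
#' order, the greedy largest prefix is the exhaustive optimum over prefixes.
#'
#' @param posteriors numeric vector in \[0, 1\].
#' @param alpha FDR bound.
#' @return list with `selected` (integer indices, possibly empty) and
#'   `expected_fdr` (mean of `1 - p` over the selected set; `NA` if empty).
#' @export
select_fdr_obf <- function(posteriors, alpha) {
  stopifnot(all(posteriors >= 0 & posteriors <= 1))
  ord <- order(posteriors, decreasing = TRUE)
  cum_err <- cumsum(1 - posteriors[ord]) / seq_along(ord)
  k <- max(c(0L, which(cum_err <= alpha)))
  if (k == 0L)
    return(list(selected = integer(0), expected_fdr = NA_real_))
  list(selected = sort(ord[seq_len(k)]), expected_fdr = cum_err[k])
}

#' Moments of the number of markers
#'
#' Treating feature identities as independent Bernoulli draws with the given
#' posterior probabilities, the number of markers has mean `sum(p)` and
#' variance `sum(p (1 - p))`.
#'
#' @param posteriors numeric vector in \[0, 1\].
#' @return list with `mean` and `sd`.
#' @export
marker_count_moments <- function(posteriors) {
  stopifnot(all(posteriors >= 0 & posteriors <= 1))
  list(mean = sum(posteriors), sd = sqrt(sum(posteriors * (1 - posteriors))))
}

#' Joint marker posterior across cancers
#'
#' Under independence of marker identity across cancers, the probability
#' that a feature is a marker in every cancer is the product of its
#' per-cancer posteriors.
#'
#' @param per_cancer_posteriors numeric matrix, features x cancers, entries
#'   in \[0, 1\] (a vector is treated as a single-cancer matrix).
#' @return numeric vector of per-feature joint probabilities.
#' @export
joint_posterior <- function(per_cancer_posteriors) {
  m <- as.matrix(per_cancer_posteriors)
  stopifnot(all(m >= 0 & m <= 1))
  apply(m, 1L, prod)
}

#' Structured multi-group OBF
#'
#' Model selection over the four ways the frozen-normal (FN), frozen-tumor
#' (FT) and FFPE-tumor (PT) groups can share a distribution:
#' A -- one distribution for all slides; B -- frozen (FN+FT) vs FFPE (PT);
#' C -- tumor (FT+PT) vs normal (FN); D -- (FN+PT) vs FT. Structure priors
#' are 0.5 for A and 0.5/3 for each of B, C, D. Each structure's marginal is
#' the product of its blocks' marginals ([block_log_marginal()]). A feature
#' is flagged `ffpe_ineffective` when the maximum a posteriori structure is
#' B and the FT and PT group means fall on opposite sides of the FN mean:
#' its apparent tumor signal is then a preparation artifact.
#'
#' @param x_fn,x_ft,x_pt numeric vectors for the three groups (each
#'   length >= 2, non-constant).
#' @param config an [obf_config()].
#' @param priors named numeric vector of structure priors summing to 1.
#' @return list with `posterior` (named A-D), `map` (name of the MAP
#'   structure), `group_means`, and `ffpe_ineffective`.
#' @export
structured_obf <- function(x_fn, x_ft, x_pt, config = obf_config(),
                           priors = c(A = 0.5, B = 0.5 / 3, C = 0.5 / 3,
                                      D = 0.5 / 3)) {
  stopifnot(abs(sum(priors) - 1) < 1e-12,
            identical(sort(names(priors)), c("A", "B", "C", "D")))
  blk <- function(x, nm) {
    if (length(x) < 2) stop("block '", nm, "' needs at least 2 observations")
    ss <- sum((x - mean(x))^2)
    if (ss <= 0) stop("degenerate variance in block '", nm, "'")
    block_log_marginal(config = config, n = length(x), ss = ss)
  }
  lm <- c(
    A = blk(c(x_fn, x_ft, x_pt), "FN+FT+PT"),
    B = blk(c(x_fn, x_ft), "FN+FT") + blk(x_pt, "PT"),
    C = blk(c(x_ft, x_pt), "FT+PT") + blk(x_fn, "FN"),
    D = blk(c(x_fn, x_pt), "FN+PT") + blk(x_ft, "FT")
  )
  lp <- log(priors[c("A", "B", "C", "D")]) + lm
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  map <- names(post)[which.max(post)]
  mu <- c(FN = mean(x_fn), FT = mean(x_ft), PT = mean(x_pt))
  straddle <- (mu["FT"] - mu["FN"]) * (mu["PT"] - mu["FN"]) < 0
  list(posterior = post, map = map, group_means = mu,
       ffpe_ineffective = unname(map == "B" && straddle))
}

# normalize assorted binary label encodings to integer 0/1
as_binary_labels <- function(labels, n) {
  if (length(labels) != n) stop("labels must have one entry per slide")
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels) || is.character(labels)) {
    u <- sort(unique(as.character(labels)))
    if (length(u) != 2) stop("labels must have exactly 2 levels")
    return(as.integer(as.character(labels) == u[2]))
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) != 2)
    stop("numeric labels must be 0/1 with both classes present")
  as.integer(labels)
}
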