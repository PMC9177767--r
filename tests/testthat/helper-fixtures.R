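# shared fixtures built in code

# minimal metadata table: n slides, one patient per slide unless stated
tiny_meta <- function(n = 4, cancer = "BRCA", lesion = rep("tumor", n),
                      preparation = rep("frozen", n),
                      patient = sprintf("P%02d", seq_len(n))) {
  slide_meta(sprintf("TCGA-%s-%04d-01A-TS%d", cancer, seq_len(n), seq_len(n)),
             patient, rep(cancer, n), lesion, preparation,
             vial_id = sprintf("V%03d", seq_len(n)))
}

# tile table from an explicit per-slide list of tile-by-feature matrices
tiles_from_list <- function(meta, per_slide) {
  stopifnot(length(per_slide) == nrow(meta))
  rows <- do.call(rbind, lapply(seq_along(per_slide), function(i) {
    m <- as.matrix(per_slide[[i]])
    data.frame(slide_id = meta$slide_id[i], tile_index = seq_len(nrow(m)) - 1L,
               m, stringsAsFactors = FALSE)
  }))
  colnames(rows) <- c("slide_id", "tile_index",
                      paste0("f", seq_len(ncol(per_slide[[1]])) - 1L))
  rows
}

# random two-class slide-level matrix, no tile stage
two_class_matrix <- function(n0, n1, M, delta = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n0 + n1) * M), n0 + n1, M,
              dimnames = list(NULL, as.character(seq_len(M) - 1L)))
  x[(n0 + 1):(n0 + n1), 1] <- x[(n0 + 1):(n0 + n1), 1] + delta
  list(x = x, labels = rep(c(0L, 1L), c(n0, n1)))
}

# quadrature oracle for the OBF block marginal: the analytic form equals
# norm_const * n^(-1/2) * integral of likelihood x (sigma^2)^(-3/2)
quad_log_marginal <- function(x, config = obf_config()) {
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  xbar <- mean(x)
  inner <- function(s2) {
    vapply(s2, function(v) {
      f <- function(mu)
        exp(-(ss + n * (mu - xbar)^2) / (2 * v) - n / 2 * log(2 * pi * v))
      stats::integrate(f, xbar - 40 * sqrt(v / n), xbar + 40 * sqrt(v / n),
                       rel.tol = 1e-10)$value * v^(-1.5)
    }, numeric(1))
  }
  # integrate over log(sigma^2) for stability
  g <- function(t) inner(exp(t)) * exp(t)
  peak <- log(ss / n)
  val <- stats::integrate(g, peak - 30, peak + 30, rel.tol = 1e-10)$value
  log(config$norm_const) - 0.5 * log(n) + log(val)
}
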