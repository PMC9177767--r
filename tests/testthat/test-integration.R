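paired_fixture <- function(n = 40, seed = 1, genes) {
  meta <- slide_meta(sprintf("S%03d", 1:n), sprintf("P%03d", 1:n),
                     rep("OV", n), rep("tumor", n), rep("frozen", n),
                     vial_id = sprintf("V%03d", 1:n))
  expr <- expression_matrix(genes, meta$vial_id, colnames(genes))
  list(meta = meta, expr = expr)
}

test_that("gene filters drop constants, zero-heavy and flat genes, keep the rest", {
  set.seed(1)
  n <- 40
  genes <- cbind(CONST = rep(2, n),
                 ZEROHEAVY = ifelse(seq_len(n) <= 0.6 * n, 0, rnorm(n, 3)),
                 FLAT = rnorm(n, 5, 0.1),
                 OK = rnorm(n, 3, 0.5),
                 SOMEZERO = c(rep(0, 4), rnorm(n - 4, 3)))
  fx <- paired_fixture(n, genes = genes)
  kept <- filter_genes(fx$expr)
  expect_setequal(colnames(kept$values), c("OK", "SOMEZERO"))
  expect_setequal(attr(kept, "dropped"), c("CONST", "ZEROHEAVY", "FLAT"))
  # idempotent
  again <- filter_genes(kept)
  expect_identical(again$values, kept$values)
  flat_only <- paired_fixture(n, genes = genes[, "FLAT", drop = FALSE])
  expect_error(filter_genes(flat_only$expr), "all genes removed")
})

test_that("a gene duplicating a mone correlates at (essentially) one", {
  set.seed(2)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("0", "1", "2")))
  genes <- cbind(COPY = x[, 2] + 3, OTHER = rnorm(n, 3))
  fx <- paired_fixture(n, genes = genes)
  mones <- mone_matrix(x, fx$meta)
  mg <- mone_gene_correlation(mones, fx$expr, alpha = 0.05)
  expect_equal(dim(mg$r), c(3, 2))
  expect_equal(mg$r_sample["1", "COPY"], 1, tolerance = 1e-12)
  expect_true(any(mg$pairs_significant$mone == "1" &
                    mg$pairs_significant$gene == "COPY"))
  expect_equal(mg$n_effective, n)
})

test_that("bicluster extraction returns planted components and nothing else", {
  # two disjoint planted blocks in a q-matrix built directly
  q <- matrix(1, 6, 6, dimnames = list(as.character(0:5),
                                       paste0("g", 1:6)))
  r <- matrix(0, 6, 6, dimnames = dimnames(q))
  q[1:2, 1:2] <- 0.001; r[1:2, 1:2] <- 0.8
  q[4:6, 4:6] <- 0.001; r[4:6, 4:6] <- -0.7
  comps <- extract_bicluster(list(r = r, q = q), alpha = 0.05)
  expect_length(comps, 2)
  sizes <- vapply(comps, function(cc) length(cc$mones) + length(cc$genes),
                  numeric(1))
  expect_setequal(sizes, c(4, 6))
  expect_equal(comps[[which(sizes == 4)]]$mean_abs_r, 0.8)
  empty <- extract_bicluster(list(r = r, q = matrix(1, 6, 6,
                                                    dimnames = dimnames(q))),
                             alpha = 0.05)
  expect_length(empty, 0)
})

test_that("cluster PC-1 matches a hand eigen-decomposition and conventions", {
  # 4 samples x 3 members
  x <- matrix(c(1, 2, 3, 4,
                2, 4.1, 5.9, 8,
                0.5, 0.9, 1.6, 2.1), 4, 3,
              dimnames = list(NULL, c("3", "1", "2")))
  cs <- cluster_pc1(x)
  ev <- eigen(cov(x))
  expect_equal(cs$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-12)
  lead <- ev$vectors[, 1]
  if (lead[which.min(as.numeric(colnames(x)))] < 0) lead <- -lead
  expect_equal(unname(cs$loadings), unname(lead), tolerance = 1e-9)
  expect_equal(sum(cs$loadings^2), 1, tolerance = 1e-12)
  expect_equal(cs$scores,
               as.numeric(scale(x, scale = FALSE) %*% lead),
               tolerance = 1e-9)

  # two perfectly correlated members
  y <- cbind(`0` = 1:6, `1` = 2 * (1:6) + 3)
  expect_equal(cluster_pc1(y)$variance_explained, 1)

  set.seed(3)
  iso <- matrix(rnorm(400 * 5), 400, 5,
                dimnames = list(NULL, as.character(0:4)))
  expect_lt(abs(cluster_pc1(iso)$variance_explained - 0.2), 0.05)
  expect_error(cluster_pc1(matrix(0, 5, 2,
                                  dimnames = list(NULL, c("0", "1")))),
               "degenerate")
})

test_that("cluster PC-1 tracks the generating latent factor", {
  cfg <- generator_config(n_cancers = 1, M = 10,
                          slides_per_group = c(tumor_frozen = 150),
                          tiles_per_slide = c(2, 4),
                          blocks = list(list(features = 0:4, rho = 0.7,
                                             cancers = "all")),
                          seed = 4)
  co <- generate_cohort(cfg)
  mones <- aggregate_tiles(co$tiles, co$meta)
  cs <- cluster_pc1(mones, members = 0:4)
  expect_gte(abs(cor(cs$scores, co$truth$factors[, 1])), 0.9)
})

test_that("covariate correlation obeys trim semantics and edge cases", {
  set.seed(5)
  score <- rnorm(100)
  aff <- 2 * score + 1
  res <- correlate_with_covariate(score, aff)
  expect_equal(res$r, 1, tolerance = 1e-12)
  ind <- correlate_with_covariate(rnorm(200), rnorm(200))
  expect_lt(abs(ind$r), 0.2)

  cov_frac <- runif(100, 0, 0.06)
  tr <- correlate_with_covariate(score, log1p(cov_frac), trim_above = 0.03,
                                 trim_on = cov_frac)
  expect_setequal(tr$trimmed, which(cov_frac > 0.03))
  expect_equal(tr$n, sum(cov_frac <= 0.03))
  expect_error(correlate_with_covariate(rnorm(3), rnorm(3)), "4 complete")
})

test_that("IG score averages member genes with coverage control", {
  n <- 10
  genes <- cbind(IGHM = rep(1, n), IGHG1 = rep(1, n), OTHER = rnorm(n))
  fx <- paired_fixture(n, genes = genes)
  expect_equal(as.numeric(ig_score(fx$expr, c("IGHM", "IGHG1"))), rep(1, n))
  expect_equal(as.numeric(ig_score(fx$expr, "OTHER")),
               unname(fx$expr$values[, "OTHER"]))
  set.seed(6)
  g2 <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  fx2 <- paired_fixture(n, genes = g2)
  loop <- sapply(seq_len(n), function(i) mean(g2[i, c("A", "C")]))
  expect_equal(as.numeric(ig_score(fx2$expr, c("A", "C"))), loop)
  expect_error(ig_score(fx2$expr, c("A", "ZZ")), "coverage")
  expect_equal(as.numeric(ig_score(fx2$expr, c("A", "ZZ"), min_coverage = 0.5)),
               unname(g2[, "A"]))
  expect_error(ig_score(fx2$expr, c("XX", "YY")), "no member gene")
})

test_that("end-to-end planted mone-gene coupling is recovered cleanly", {
  recalls <- contams <- numeric(0)
  for (s in 1:5) {
    cfg <- generator_config(n_cancers = 1, M = 25,
                            slides_per_group = c(tumor_frozen = 300),
                            tiles_per_slide = c(2, 4),
                            blocks = list(list(features = 0:4, rho = 0.7,
                                               cancers = "all")),
                            genes = list(n_null = 200,
                                         coupled = data.frame(
                                           target_type = "factor",
                                           target = rep(1, 5), r = 0.7),
                                         n_lowsd = 3, n_zero = 3),
                            seed = 1000 + s)
    co <- generate_cohort(cfg)
    mones <- aggregate_tiles(co$tiles, co$meta)
    expr <- generate_expression(co$truth, co$meta, cfg)
    mg <- mone_gene_correlation(mones, filter_genes(expr), 0.05)
    comps <- extract_bicluster(mg, 0.05)
    genes_found <- unique(unlist(lapply(comps, `[[`, "genes")))
    recalls <- c(recalls, mean(sprintf("COUPLED%03d", 1:5) %in% genes_found))
    contams <- c(contams,
                 if (length(genes_found) == 0) 0
                 else mean(!grepl("^COUPLED", genes_found)))
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(contams), 0.05)
})
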