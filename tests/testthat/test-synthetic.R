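test_that("the generator is fully deterministic given the seed", {
  cfg <- generator_config(n_cancers = 2, M = 10,
                          slides_per_group = c(tumor_frozen = 6,
                                               normal_frozen = 6),
                          genes = list(n_null = 8), seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$tiles, b$tiles)
  expect_identical(as.data.frame(a$meta), as.data.frame(b$meta))
  expect_identical(a$truth$factors, b$truth$factors)
  ea <- generate_expression(a$truth, a$meta, cfg)
  eb <- generate_expression(b$truth, b$meta, cfg)
  expect_identical(ea$values, eb$values)
  c3 <- generate_cohort(generator_config(n_cancers = 2, M = 10,
                                         slides_per_group = c(tumor_frozen = 6,
                                                              normal_frozen = 6),
                                         genes = list(n_null = 8), seed = 43))
  expect_false(identical(a$tiles$f0, c3$tiles$f0))
})

test_that("config validation rejects impossible specifications", {
  expect_error(generator_config(slides_per_group = c(bad_name = 3)),
               "slides_per_group")
  expect_error(generator_config(blocks = list(list(features = 0:2, rho = 1.2,
                                                   cancers = "all"))),
               "rho")
  expect_error(generator_config(markers = data.frame(feature = 0,
                                                     cancer = "all",
                                                     delta = 1,
                                                     var_ratio = -2)),
               "variance ratio")
})

test_that("a markerless cohort is null: t-test rejections track alpha", {
  cfg <- generator_config(n_cancers = 1, M = 2000,
                          slides_per_group = c(tumor_frozen = 25,
                                               normal_frozen = 25),
                          tiles_per_slide = c(4, 8), seed = 7)
  co <- generate_cohort(cfg)
  mones <- aggregate_tiles(co$tiles, co$meta)
  res <- run_tests(mones, mones$meta$lesion, tests = "t")
  rej <- mean(res$p_t <= 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # class-mean differences center on zero
  expect_lt(abs(mean(res$direction)), 0.1)
})

test_that("a 2-sd marker at 100 vs 100 slides is overwhelmingly significant", {
  for (s in 1:3) {
    cfg <- generator_config(n_cancers = 1, M = 40,
                            slides_per_group = c(tumor_frozen = 100,
                                                 normal_frozen = 100),
                            tiles_per_slide = c(3, 6),
                            markers = data.frame(feature = 0, cancer = "all",
                                                 delta = 2),
                            seed = 500 + s)
    co <- generate_cohort(cfg)
    mones <- aggregate_tiles(co$tiles, co$meta)
    res <- run_tests(mones, mones$meta$lesion, tests = "t")
    expect_lt(res$q_t[1], 1e-10)
  }
})

test_that("target a(m) parametrization realizes the requested effect size", {
  target <- 1.3
  ams <- vapply(1:30, function(s) {
    cfg <- generator_config(n_cancers = 1, M = 1,
                            slides_per_group = c(tumor_frozen = 60,
                                                 normal_frozen = 60),
                            tiles_per_slide = c(2, 3), tile_sd = 0,
                            markers = data.frame(feature = 0, cancer = "all",
                                                 target_am = target),
                            seed = 900 + s)
    co <- generate_cohort(cfg)
    mones <- aggregate_tiles(co$tiles, co$meta)
    am_statistic(mones$values[mones$meta$lesion == "normal", 1],
                 mones$values[mones$meta$lesion == "tumor", 1])
  }, numeric(1))
  mc_err <- 3 * sd(ams) / sqrt(length(ams))
  expect_lt(abs(mean(ams) - target), mc_err + 0.02)
})

test_that("block features converge to the specified correlation", {
  cfg <- generator_config(n_cancers = 1, M = 6,
                          slides_per_group = c(tumor_frozen = 800),
                          tiles_per_slide = c(2, 3), tile_sd = 0.05,
                          blocks = list(list(features = 0:2, rho = 0.6,
                                             cancers = "all")),
                          seed = 31)
  co <- generate_cohort(cfg)
  mones <- aggregate_tiles(co$tiles, co$meta)
  r <- cor(mones$values)
  block <- r[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  expect_true(all(abs(block - 0.6) < 0.08))
  outside <- r[1:3, 4:6]
  expect_lt(max(abs(outside)), 0.12)
})

test_that("coupled genes realize the target correlation with their factor", {
  ok <- 0
  for (s in 1:10) {
    cfg <- generator_config(n_cancers = 1, M = 4,
                            slides_per_group = c(tumor_frozen = 300),
                            tiles_per_slide = c(2, 3),
                            blocks = list(list(features = 0:1, rho = 0.5,
                                               cancers = "all")),
                            genes = list(coupled = data.frame(
                              target_type = "factor", target = 1, r = 0.8)),
                            seed = 40 + s)
    co <- generate_cohort(cfg)
    expr <- generate_expression(co$truth, co$meta, cfg)
    realized <- cor(expr$values[, 1], co$truth$factors[, 1])
    ok <- ok + (abs(realized - 0.8) <= 0.08)
  }
  expect_gte(ok, 9)  # sampling-error envelope: ~95% of seeds inside
})

test_that("filter-exercising genes are produced and removed as designed", {
  cfg <- generator_config(n_cancers = 1, M = 3,
                          slides_per_group = c(tumor_frozen = 40),
                          tiles_per_slide = c(2, 3),
                          genes = list(n_null = 10, n_lowsd = 4, n_zero = 4),
                          seed = 77)
  co <- generate_cohort(cfg)
  expr <- generate_expression(co$truth, co$meta, cfg)
  kept <- filter_genes(expr)
  dropped <- attr(kept, "dropped")
  expect_true(all(grepl("LOWSD|ZERO", dropped)))
  expect_true(all(grepl("NULL", colnames(kept$values))))
})

test_that("null gene couplings produce no significant mone-gene pairs", {
  cfg <- generator_config(n_cancers = 1, M = 20,
                          slides_per_group = c(tumor_frozen = 120),
                          tiles_per_slide = c(2, 3),
                          genes = list(n_null = 150), seed = 88)
  co <- generate_cohort(cfg)
  mones <- aggregate_tiles(co$tiles, co$meta)
  expr <- generate_expression(co$truth, co$meta, cfg)
  mg <- mone_gene_correlation(mones, filter_genes(expr), 0.05)
  expect_lte(nrow(mg$pairs_significant), 2)
})

test_that("paired patients reuse tumor patients for normal slides", {
  cfg <- generator_config(n_cancers = 1, M = 2,
                          slides_per_group = c(tumor_frozen = 10,
                                               normal_frozen = 6),
                          paired_patients = TRUE, seed = 5)
  co <- generate_cohort(cfg)
  tum <- unique(co$meta$patient_id[co$meta$lesion == "tumor"])
  nor <- unique(co$meta$patient_id[co$meta$lesion == "normal"])
  expect_true(all(nor %in% tum))
})
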