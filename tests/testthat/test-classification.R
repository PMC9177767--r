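make_class_cohort <- function(n_per_class = 20, classes = c("a", "b"),
                              M = 10, sep = 5, seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  cls <- rep(classes, each = n_per_class)
  x <- matrix(rnorm(n * M), n, M,
              dimnames = list(NULL, as.character(seq_len(M) - 1L)))
  for (k in seq_along(classes))
    x[cls == classes[k], k] <- x[cls == classes[k], k] + sep
  meta <- slide_meta(sprintf("S%03d", seq_len(n)),
                     sprintf("P%03d", seq_len(n)),
                     rep("SYN", n), rep("tumor", n), rep("frozen", n),
                     vial_id = sprintf("V%03d", seq_len(n)))
  list(x = x, class = cls, meta = meta)
}

test_that("splits are patient-grouped, stratified, and deterministic", {
  n <- 16
  meta <- slide_meta(sprintf("S%02d", 1:n), sprintf("P%02d", rep(1:8, each = 2)),
                     rep("SYN", n), rep("tumor", n), rep("frozen", n),
                     vial_id = sprintf("V%02d", 1:n))
  cls <- rep(c("a", "b"), each = 8)  # patients are class-pure
  plan <- make_splits(meta, cls, n_reps = 10, test_fraction = 0.25, seed = 3)
  for (rep in plan$reps) {
    expect_setequal(c(rep$train, rep$test), 1:n)
    expect_length(intersect(meta$patient_id[rep$train],
                            meta$patient_id[rep$test]), 0)
    for (cl in c("a", "b"))
      expect_equal(sum(cls[rep$test] == cl), 2)  # 25% of 8 slides
  }
  plan2 <- make_splits(meta, cls, n_reps = 10, test_fraction = 0.25, seed = 3)
  expect_identical(plan$reps, plan2$reps)
  expect_false(identical(plan$reps,
                         make_splits(meta, cls, 10, 0.25, seed = 4)$reps))
})

test_that("two patients per class at half test fraction puts one on each side", {
  meta <- slide_meta(c("s1", "s2", "s3", "s4"), c("p1", "p2", "p3", "p4"),
                     rep("SYN", 4), rep("tumor", 4), rep("frozen", 4),
                     vial_id = c("v1", "v2", "v3", "v4"))
  cls <- c("a", "a", "b", "b")
  plan <- make_splits(meta, cls, n_reps = 5, test_fraction = 0.5, seed = 1)
  for (rep in plan$reps) {
    expect_equal(sum(cls[rep$test] == "a"), 1)
    expect_equal(sum(cls[rep$test] == "b"), 1)
  }
  expect_error(make_splits(meta, c("a", "a", "a", "b"), seed = 1), "b")
})

test_that("MLDA separates well-separated classes and not permuted labels", {
  ch <- make_class_cohort(n_per_class = 20, sep = 5, seed = 2)
  sp <- make_splits(ch$meta, ch$class, n_reps = 1, test_fraction = 0.3,
                    seed = 2)$reps[[1]]
  fit <- fit_mlda(ch$x[sp$train, ], ch$class[sp$train])
  ev <- evaluate_classifier(fit, ch$x[sp$test, ], ch$class[sp$test])
  expect_equal(unname(ev$auc), c(1, 1))
  expect_equal(rowSums(ev$confusion), c(a = 1, b = 1))

  set.seed(9)
  perm <- sample(ch$class)
  aucs <- vapply(1:5, function(s) {
    spp <- make_splits(ch$meta, perm, n_reps = 1, 0.3, seed = s)$reps[[1]]
    f <- fit_mlda(ch$x[spp$train, ], perm[spp$train])
    evaluate_classifier(f, ch$x[spp$test, ], perm[spp$test])$macro_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("LR-LASSO returns proper probabilities and is sparse on nulls", {
  ch <- make_class_cohort(n_per_class = 30, M = 500, sep = 0, seed = 3)
  # one informative feature among 500
  ch$x[, 7] <- ch$x[, 7] + ifelse(ch$class == "a", 0, 3)
  nz_hits <- 0; nz_counts <- integer(0)
  for (s in 1:10) {
    sp <- make_splits(ch$meta, ch$class, n_reps = 1, 0.25,
                      seed = 100 + s)$reps[[1]]
    fit <- fit_lr_lasso(ch$x[sp$train, ], ch$class[sp$train], C = 100)
    pr <- predict(fit, ch$x[sp$test, ])
    expect_equal(rowSums(pr$posterior), rep(1, length(sp$test)),
                 tolerance = 1e-9)
    nz_hits <- nz_hits + ("6" %in% fit$nonzero)
    nz_counts <- c(nz_counts, length(fit$nonzero))
  }
  expect_gte(nz_hits, 9)
  expect_lte(median(nz_counts), 25)
})

test_that("AUCs barely move across C in {1, 100, 1000} on separable data", {
  ch <- make_class_cohort(n_per_class = 25, sep = 4, seed = 4)
  sp <- make_splits(ch$meta, ch$class, n_reps = 1, 0.3, seed = 1)$reps[[1]]
  aucs <- vapply(c(1, 100, 1000), function(C) {
    fit <- fit_lr_lasso(ch$x[sp$train, ], ch$class[sp$train], C = C)
    evaluate_classifier(fit, ch$x[sp$test, ], ch$class[sp$test])$macro_auc
  }, numeric(1))
  expect_lt(max(aucs) - min(aucs), 0.01)
})

test_that("rank AUC equals the exhaustive pairwise concordance count", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 1)  # ties occur
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    brute <- 0; total <- 0
    for (a in which(y)) for (b in which(!y)) {
      total <- total + 1
      brute <- brute + (scores[a] > scores[b]) + 0.5 * (scores[a] == scores[b])
    }
    expect_equal(ovr_auc(scores, y), brute / total, tolerance = 1e-12)
  }
  expect_equal(ovr_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_true(is.na(ovr_auc(rnorm(5), rep(FALSE, 5))))
})

test_that("universal tumor score sums tumor-class probabilities", {
  ch <- make_class_cohort(n_per_class = 15, classes = c("x_tumor", "x_normal",
                                                        "y_tumor", "y_normal"),
                          M = 8, sep = 4, seed = 6)
  fit <- fit_lr_lasso(ch$x, ch$class, C = 100)
  sc <- universal_tumor_score(fit, ch$x, c("x_tumor", "y_tumor"))
  expect_true(all(sc >= 0 & sc <= 1))
  is_tumor <- grepl("tumor", ch$class)
  expect_gt(ovr_auc(sc, is_tumor), 0.95)
  expect_error(universal_tumor_score(fit, ch$x, c("x_tumor", "zz")), "zz")
})

test_that("cross-classification transfers when markers are shared, not when disjoint", {
  set.seed(7)
  n <- 40  # per (cancer, lesion)
  build <- function(shared) {
    meta <- NULL; xs <- NULL
    for (ci in c("AA", "BB")) {
      cls <- rep(c("tumor", "normal"), each = n)
      x <- matrix(rnorm(2 * n * 6), 2 * n, 6,
                  dimnames = list(NULL, as.character(0:5)))
      col <- if (shared || ci == "AA") 1 else 4
      x[cls == "tumor", col] <- x[cls == "tumor", col] + 3
      m <- slide_meta(sprintf("%s-S%03d", ci, 1:(2 * n)),
                      sprintf("%s-P%03d", ci, 1:(2 * n)),
                      rep(ci, 2 * n), cls, rep("frozen", 2 * n),
                      vial_id = sprintf("%s-V%03d", ci, 1:(2 * n)))
      meta <- if (is.null(meta)) as.data.frame(m)
              else rbind(meta, as.data.frame(m))
      xs <- rbind(xs, x)
    }
    meta <- slide_meta(meta$slide_id, meta$patient_id, meta$cancer_type,
                       meta$lesion, meta$preparation, meta$vial_id)
    mone_matrix(xs, meta)
  }
  shared <- cross_classification(build(TRUE), seed = 1)
  expect_true(all(diag(shared) > 0.95))
  expect_true(all(shared > 0.9))
  disjoint <- cross_classification(build(FALSE), seed = 1)
  expect_gt(disjoint["AA", "AA"], 0.95)
  expect_gt(disjoint["BB", "BB"], 0.95)
  expect_lt(abs(disjoint["AA", "BB"] - 0.5), 0.25)
  expect_lt(abs(disjoint["BB", "AA"] - 0.5), 0.25)
})

test_that("clustermap metrics are exact on separated data and near zero on noise", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 8), 20, 3))
  lab <- rep(c(0, 1), each = 20)
  m <- clustermap_metrics(x, lab)
  expect_equal(m$auc, 1)
  expect_equal(m$rand, 1)
  expect_equal(m$adjusted_rand, 1)

  aris <- vapply(1:10, function(i) {
    clustermap_metrics(matrix(rnorm(40 * 3), 40, 3),
                       sample(rep(c(0, 1), 20)))$adjusted_rand
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
})

test_that("rand index matches its pair-counting formula on small instances", {
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:2, 20, replace = TRUE)
    agree <- 0
    for (p in 1:19) for (q in (p + 1):20)
      agree <- agree + ((a[p] == a[q]) == (b[p] == b[q]))
    expect_equal(monekit:::rand_index(a, b), agree / choose(20, 2))
    expect_gte(monekit:::rand_index(a, b), 0)
    expect_lte(monekit:::rand_index(a, b), 1)
  }
})

test_that("t-SNE embedding keeps duplicated clouds co-located and is reproducible", {
  set.seed(10)
  base <- matrix(rnorm(60 * 3), 60, 3)
  cloud <- rbind(base, base + matrix(rnorm(180, 0, 0.01), 60, 3))
  emb <- embed_mlda_tsne(cloud, perplexity = 10, seed = 1)
  # nearest neighbor in the embedding should be the duplicate partner often
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  partner <- c(61:120, 1:60)
  expect_gte(mean(nn == partner), 0.5)
  emb2 <- embed_mlda_tsne(cloud, perplexity = 10, seed = 1)
  expect_identical(emb, emb2)
  one_d <- matrix(rnorm(30), 30, 1)
  expect_warning(e1 <- embed_mlda_tsne(one_d, perplexity = 50, seed = 1),
                 "perplexity")
  expect_equal(dim(e1), c(30, 2))
})
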