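#' Patient-level stratified Monte Carlo splits
#'
#' Builds `n_reps` random train/test partitions of the slides such that no
#' patient ever appears on both sides of a split and per-class train/test
#' proportions track the requested test fraction. Patients are the atomic
#' unit: all of a patient's slides travel together. When every patient's
#' slides belong to a single class the per-class test counts are met to
#' within the patient's slide count (exactly, for one-slide patients);
#' patients spanning classes are assigned once and counted against each of
#' their classes.
#'
#' @param meta a [slide_meta()] table.
#' @param class character vector of class labels, one per slide (e.g.
#'   `paste(cancer_type, lesion)`); defaults to `lesion`.
#' @param n_reps number of repetitions.
#' @param test_fraction fraction of slides per class assigned to test.
#' @param seed integer seed; the plan is deterministic given it.
#' @return object of class `split_plan`: list of `n_reps` lists with
#'   integer `train` and `test` slide indices, plus the constraint record.
#' @export
make_splits <- function(meta, class = NULL, n_reps = 10, test_fraction = 0.25,
                        seed = 1) {
  stopifnot(inherits(meta, "slide_meta"), test_fraction > 0,
            test_fraction < 1, n_reps >= 1)
  if (is.null(class)) class <- meta$lesion
  class <- as.character(class)
  stopifnot(length(class) == nrow(meta))
  pat_by_class <- tapply(meta$patient_id, class, function(p) unique(p))
  single <- names(pat_by_class)[vapply(pat_by_class, length, 1L) < 2]
  if (length(single))
    stop("classes with fewer than 2 patients: ",
         paste(single, collapse = ", "))
  set.seed(seed)
  classes <- names(sort(table(class)))  # rarest first: their targets bind most
  reps <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    side <- character(0)  # patient -> "test" / "train"
    for (cl in classes) {
      rows <- which(class == cl)
      target <- round(test_fraction * length(rows))
      target <- min(max(target, 1L), length(rows) - 1L)
      pats <- unique(meta$patient_id[rows])
      n_by_pat <- table(factor(meta$patient_id[rows], levels = pats))
      cur <- sum(n_by_pat[names(n_by_pat) %in% names(side)[side == "test"]])
      todo <- sample(setdiff(pats, names(side)))
      for (p in todo) {
        k <- n_by_pat[[p]]
        if (cur < target && abs(cur + k - target) <= abs(cur - target)) {
          side[p] <- "test"; cur <- cur + k
        } else side[p] <- "train"
      }
    }
    test_pat <- names(side)[side == "test"]
    test <- which(meta$patient_id %in% test_pat)
    reps[[rep_i]] <- list(train = setdiff(seq_len(nrow(meta)), test),
                          test = test)
  }
  structure(list(reps = reps, class = class, test_fraction = test_fraction,
                 seed = seed, grouping = "patient"),
            class = "split_plan")
}

#' Multi-class linear discriminant analysis
#'
#' Fits LDA on the training slides and exposes both class posteriors (under
#' the equal-covariance Gaussian model) and the (k-1)-dimensional
#' discriminant projection. `MASS::lda` is the solver; when it fails on a
#' singular within-class scatter, a shrinkage fallback (pooled within-class
#' covariance blended with its average diagonal) is used and a message is
#' emitted.
#'
#' @param x numeric matrix (slides x features) or [mone_matrix()].
#' @param labels class labels (factor or character), >= 2 classes with >= 2
#'   slides each.
#' @return object of class `mlda_model`.
#' @export
fit_mlda <- function(x, labels) {
  x <- if (inherits(x, "mone_matrix")) x$values else as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 slides")
  fit <- tryCatch(suppressWarnings(MASS::lda(x, grouping = y)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    message("within-class scatter singular; using shrinkage MLDA fallback")
    fit <- mlda_shrunk(x, y)
  }
  structure(list(fit = fit, classes = levels(y)), class = "mlda_model")
}

# manual MLDA with diagonal shrinkage of the pooled within-class covariance
mlda_shrunk <- function(x, y, gamma = 0.01) {
  k <- nlevels(y); p <- ncol(x)
  mus <- t(vapply(levels(y), function(l) colMeans(x[y == l, , drop = FALSE]),
                  numeric(p)))
  W <- matrix(0, p, p)
  for (l in levels(y)) {
    xs <- x[y == l, , drop = FALSE]
    W <- W + crossprod(sweep(xs, 2L, colMeans(xs)))
  }
  W <- W / (nrow(x) - k)
  W <- (1 - gamma) * W + gamma * mean(diag(W)) * diag(p)
  structure(list(means = mus, W_inv = solve(W), levels = levels(y),
                 prior = as.numeric(table(y) / length(y))),
            class = "mlda_shrunk")
}

#' @export
predict.mlda_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "mone_matrix")) newdata$values
       else as.matrix(newdata)
  if (inherits(object$fit, "mlda_shrunk")) {
    f <- object$fit
    disc <- x %*% f$W_inv %*% t(f$means) -
      matrix(0.5 * rowSums((f$means %*% f$W_inv) * f$means),
             nrow(x), length(f$levels), byrow = TRUE)
    disc <- sweep(disc, 2L, -log(f$prior))
    post <- exp(disc - apply(disc, 1L, max))
    post <- post / rowSums(post)
    colnames(post) <- f$levels
    proj <- x %*% f$W_inv %*% t(f$means)  # class-score space stand-in
    cls <- f$levels[max.col(post)]
  } else {
    pr <- stats::predict(object$fit, x)
    post <- pr$posterior
    proj <- pr$x
    cls <- as.character(pr$class)
  }
  list(posterior = post, projection = proj, class = cls)
}

#' L1-penalized multinomial logistic regression
#'
#' Multinomial (or binomial, for two classes) logistic regression with an
#' L1 penalty at fixed strength `1/C`, via `glmnet` with
#' `lambda = 1/(C * n)` so the penalty scale matches the
#' sum-of-log-losses parametrization used by scikit-learn's
#' `LogisticRegression(C=...)`. Coefficients with absolute value below
#' 1e-8 are reported as zero.
#'
#' @param x numeric matrix (slides x features) or [mone_matrix()].
#' @param labels class labels.
#' @param C inverse penalty strength (default 100).
#' @return object of class `lasso_model` with elements `fit`, `classes`,
#'   `lambda`, and `nonzero` (character vector of features with a nonzero
#'   coefficient in any class).
#' @export
fit_lr_lasso <- function(x, labels, C = 100) {
  x <- if (inherits(x, "mone_matrix")) x$values else as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 slides")
  lam <- 1 / (C * nrow(x))
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  # warm-started path from the KKT lambda_max down to the target lambda:
  # coordinate descent cold-started at one small penalty often stalls
  ybin <- stats::model.matrix(~ y - 1)
  ybin <- sweep(ybin, 2L, colMeans(ybin))
  lam_max <- 1.1 * max(abs(crossprod(x, ybin))) / nrow(x)
  path <- if (lam >= lam_max) sort(unique(c(lam_max * 1.01, lam)),
                                   decreasing = TRUE)
          else exp(seq(log(lam_max), log(lam), length.out = 30))
  fit <- glmnet::glmnet(x, y, family = fam, alpha = 1, lambda = path,
                        standardize = FALSE)
  if (min(fit$lambda) > lam * 1.0001)
    warning(sprintf(paste0("penalty path terminated early at lambda = %.3g ",
                           "(target %.3g); coefficients from the smallest ",
                           "converged penalty are used"),
                    min(fit$lambda), lam))
  cf <- glmnet::coef.glmnet(fit, s = lam)
  if (!is.list(cf)) cf <- list(cf)
  nz <- unique(unlist(lapply(cf, function(m) {
    v <- as.matrix(m)[-1, 1]  # drop intercept
    names(v)[abs(v) > 1e-8]
  })))
  structure(list(fit = fit, classes = levels(y), lambda = lam, C = C,
                 nonzero = nz), class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "mone_matrix")) newdata$values
       else as.matrix(newdata)
  if (length(object$classes) == 2) {
    p1 <- as.numeric(stats::predict(object$fit, x, s = object$lambda,
                                    type = "response"))
    post <- cbind(1 - p1, p1)
    colnames(post) <- object$classes
  } else {
    post <- stats::predict(object$fit, x, s = object$lambda,
                           type = "response")[, , 1]
    post <- post[, object$classes, drop = FALSE]
  }
  list(posterior = post, class = object$classes[max.col(post)])
}

#' One-versus-rest AUC by the rank statistic
#'
#' @param scores numeric scores (larger = more class-positive).
#' @param positive logical/0-1 vector marking the positive class.
#' @return AUC in \[0, 1\] (ties get average rank, so constant scores give
#'   0.5); `NA` if either group is empty.
#' @export
ovr_auc <- function(scores, positive) {
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on held-out slides
#'
#' Per-class one-versus-rest AUC from the class's posterior-probability
#' column, macro average over classes present in the test set, and the
#' row-normalized confusion matrix of argmax predictions.
#'
#' @param model an `mlda_model` or `lasso_model`.
#' @param x test slides (matrix or [mone_matrix()]).
#' @param labels true class labels for the test slides.
#' @return list with `auc` (named per-class, `NA` for absent classes),
#'   `macro_auc`, `confusion` (rows = true classes, rows sum to 1), and
#'   `predicted`.
#' @export
evaluate_classifier <- function(model, x, labels) {
  y <- as.character(labels)
  if (length(y) == 0) stop("test set is empty")
  pr <- stats::predict(model, x)
  post <- pr$posterior
  classes <- model$classes
  auc <- vapply(classes, function(cl) {
    if (!cl %in% y) return(NA_real_)
    ovr_auc(post[, cl], y == cl)
  }, numeric(1))
  pred <- classes[max.col(post)]
  present <- intersect(classes, unique(y))
  conf <- matrix(0, length(present), length(classes),
                 dimnames = list(present, classes))
  for (cl in present) {
    tab <- table(factor(pred[y == cl], levels = classes))
    conf[cl, ] <- as.numeric(tab) / sum(tab)
  }
  list(auc = auc, macro_auc = mean(auc, na.rm = TRUE), confusion = conf,
       predicted = pred)
}

#' Monte Carlo cross-validated classifier report
#'
#' Fits and evaluates a classifier over the repetitions of a patient-level
#' [make_splits()] plan.
#'
#' @param mones a [mone_matrix()].
#' @param class per-slide class labels.
#' @param model `"mlda"` or `"lasso"`.
#' @param splits a `split_plan`; built from `n_reps`/`test_fraction`/`seed`
#'   when `NULL`.
#' @param n_reps,test_fraction,seed split parameters used when `splits` is
#'   `NULL`.
#' @param C inverse L1 penalty for the lasso model.
#' @return list of class `classifier_report`: per-rep per-class AUC matrix,
#'   `macro_auc` mean and sd, pooled row-normalized confusion, and (lasso)
#'   per-rep nonzero coefficient sets.
#' @export
monte_carlo_cv <- function(mones, class, model = c("mlda", "lasso"),
                           splits = NULL, n_reps = 10, test_fraction = 0.25,
                           seed = 1, C = 100) {
  model <- match.arg(model)
  stopifnot(inherits(mones, "mone_matrix"))
  class <- as.character(class)
  if (is.null(splits))
    splits <- make_splits(mones$meta, class, n_reps = n_reps,
                          test_fraction = test_fraction, seed = seed)
  classes <- sort(unique(class))
  auc_mat <- matrix(NA_real_, length(splits$reps), length(classes),
                    dimnames = list(NULL, classes))
  conf_counts <- matrix(0, length(classes), length(classes),
                        dimnames = list(classes, classes))
  nonzero <- list()
  for (i in seq_along(splits$reps)) {
    sp <- splits$reps[[i]]
    xtr <- mones$values[sp$train, , drop = FALSE]
    xte <- mones$values[sp$test, , drop = FALSE]
    fit <- if (model == "mlda") fit_mlda(xtr, class[sp$train])
           else fit_lr_lasso(xtr, class[sp$train], C = C)
    ev <- evaluate_classifier(fit, xte, class[sp$test])
    auc_mat[i, names(ev$auc)] <- ev$auc
    yte <- class[sp$test]
    for (cl in intersect(classes, unique(yte)))
      conf_counts[cl, ] <- conf_counts[cl, ] +
        table(factor(ev$predicted[yte == cl], levels = classes))
    if (model == "lasso") nonzero[[i]] <- fit$nonzero
  }
  macro <- rowMeans(auc_mat, na.rm = TRUE)
  conf <- conf_counts / pmax(rowSums(conf_counts), 1)
  structure(list(auc = auc_mat, macro_auc_mean = mean(macro),
                 macro_auc_sd = stats::sd(macro), confusion = conf,
                 nonzero = nonzero, model = model, splits = splits),
            class = "classifier_report")
}

#' Universal tumor score from a multi-class classifier
#'
#' Sums the predicted probabilities of all tumor classes; under the
#' 2-classes-per-cancer scheme this collapses the multi-class classifier
#' into a single pan-cancer tumor detector.
#'
#' @param model a fitted classifier whose classes include `tumor_classes`.
#' @param x slides to score.
#' @param tumor_classes character vector of the tumor class labels.
#' @return numeric per-slide score in \[0, 1\].
#' @export
universal_tumor_score <- function(model, x, tumor_classes) {
  missing <- setdiff(tumor_classes, model$classes)
  if (length(missing))
    stop("class scheme mismatch; classifier lacks classes: ",
         paste(missing, collapse = ", "))
  post <- stats::predict(model, x)$posterior
  rowSums(post[, tumor_classes, drop = FALSE])
}

#' Cross-classification AUC matrix
#'
#' Trains a binary tumor/normal classifier per cancer and evaluates every
#' classifier on every cancer's slides. The diagonal is the within-cancer
#' held-out AUC (patient-level split); off-diagonal entries use the full
#' target cohort.
#'
#' @param mones a [mone_matrix()] covering all cancers.
#' @param model `"lasso"` (default) or `"mlda"`.
#' @param test_fraction held-out fraction for the diagonal entries.
#' @param seed integer seed.
#' @param C inverse L1 penalty.
#' @return numeric matrix, train cancer x test cancer.
#' @export
cross_classification <- function(mones, model = c("lasso", "mlda"),
                                 test_fraction = 0.25, seed = 1, C = 100) {
  model <- match.arg(model)
  stopifnot(inherits(mones, "mone_matrix"))
  meta <- mones$meta
  cancers <- sort(unique(meta$cancer_type))
  out <- matrix(NA_real_, length(cancers), length(cancers),
                dimnames = list(cancers, cancers))
  for (ci in cancers) {
    rows <- which(meta$cancer_type == ci)
    sub <- subset_mones(mones, rows)
    sp <- make_splits(sub$meta, sub$meta$lesion, n_reps = 1,
                      test_fraction = test_fraction, seed = seed)$reps[[1]]
    xtr <- sub$values[sp$train, , drop = FALSE]
    fit <- if (model == "lasso")
      fit_lr_lasso(xtr, sub$meta$lesion[sp$train], C = C)
    else fit_mlda(xtr, sub$meta$lesion[sp$train])
    for (cj in cancers) {
      if (cj == ci) {
        xte <- sub$values[sp$test, , drop = FALSE]
        yte <- sub$meta$lesion[sp$test]
      } else {
        rows_j <- which(meta$cancer_type == cj)
        xte <- mones$values[rows_j, , drop = FALSE]
        yte <- meta$lesion[rows_j]
      }
      post <- stats::predict(fit, xte)$posterior
      out[ci, cj] <- ovr_auc(post[, "tumor"], yte == "tumor")
    }
  }
  out
}

# rand index: pair-counting agreement between two partitions
rand_index <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

#' Cluster-separation metrics for a feature-restricted clustermap
#'
#' Hierarchically clusters slides (average linkage, Euclidean distance) on
#' the selected features, cuts the tree into two clusters, and compares the
#' clustering with the binary labels: Rand score, adjusted Rand score, and
#' an AUC obtained by scoring each slide with its cluster's fraction of
#' positive labels.
#'
#' @param x slides x selected-features matrix (or [mone_matrix()]).
#' @param labels binary labels (tumor/normal).
#' @return list with `auc`, `rand`, `adjusted_rand`, and `clusters`.
#' @export
clustermap_metrics <- function(x, labels) {
  x <- if (inherits(x, "mone_matrix")) x$values else as.matrix(x)
  lab <- as_binary_labels(labels, nrow(x))
  if (min(table(lab)) < 2) stop("need at least 2 slides per class")
  hc <- stats::hclust(stats::dist(x), method = "average")
  cl <- stats::cutree(hc, k = 2)
  if (length(unique(cl)) < 2)
    warning("degenerate cut: a single cluster")
  score <- stats::ave(lab, cl)  # per-slide tumor fraction of its cluster
  list(auc = ovr_auc(score, lab == 1L),
       rand = rand_index(cl, lab),
       adjusted_rand = mclust::adjustedRandIndex(cl, lab),
       clusters = cl)
}

#' t-SNE embedding of the discriminant space
#'
#' Embeds the (k-1)-dimensional MLDA projection in 2-D with t-SNE at
#' perplexity 50 (the effective neighbor count) and PCA initialization for
#' reproducibility. Visualization aid only.
#'
#' @param projected numeric matrix of discriminant coordinates.
#' @param perplexity t-SNE perplexity; shrunk with a warning when the
#'   sample is too small for it.
#' @param seed integer seed.
#' @return n x 2 matrix of embedding coordinates.
#' @export
embed_mlda_tsne <- function(projected, perplexity = 50, seed = 1) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("the 'Rtsne' package is required for t-SNE embedding")
  x <- as.matrix(projected)
  x <- x[, apply(x, 2L, stats::var) > 0 | seq_len(ncol(x)) == 1, drop = FALSE]
  max_perp <- floor((nrow(x) - 1) / 3)
  if (perplexity > max_perp) {
    warning("perplexity ", perplexity, " too large for ", nrow(x),
            " samples; using ", max_perp)
    perplexity <- max_perp
  }
  pc <- stats::prcomp(x, rank. = 2)$x
  if (ncol(pc) < 2) pc <- cbind(pc, 0)
  pc <- pc / max(stats::sd(pc[, 1]), 1e-12) * 1e-4  # t-SNE-scale init
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, Y_init = pc,
                      pca = FALSE, check_duplicates = FALSE)
  fit$Y
}
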