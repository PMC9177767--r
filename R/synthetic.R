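#' Synthetic cohort generator configuration
#'
#' Describes a multi-cancer cohort with the statistical structure the
#' analysis stack assumes: slide-level Gaussian feature values (markers
#' shift the tumor-class mean and may scale its variance), block-correlated
#' feature clusters driven by shared latent factors, optional structured
#' frozen/FFPE group effects, and independent tile-level noise on top of the
#' slide signal so that median aggregation is exercised nontrivially.
#' All randomness is controlled by a single seed; the expression and
#' covariate stages draw from sub-seeds derived from it so each stage can be
#' regenerated independently.
#'
#' @param n_cancers number of cancer types (names auto-generated as
#'   `C01..`) unless `cancers` is given.
#' @param cancers optional character vector of cancer type codes.
#' @param slides_per_group named integer vector with names among
#'   `tumor_frozen`, `normal_frozen`, `tumor_FFPE`, `normal_FFPE`: slides in
#'   each (lesion, preparation) group, per cancer.
#' @param tiles_per_slide length-2 integer range of tiles per slide.
#' @param M number of features.
#' @param tile_sd standard deviation of tile-level noise around the slide
#'   value (slide-level signal has unit scale).
#' @param markers optional data.frame with columns `feature` (0-based id),
#'   `cancer` (code or `"all"`), and one of `delta` (mean shift, in
#'   slide-level sd units) or `target_am` (desired a(m); converted via
#'   [am_to_delta()] at the group sizes), plus optional `var_ratio`
#'   (affected-class variance ratio, default 1) and `lesion` (which slides
#'   receive the effect: `"tumor"` (default), `"normal"`, or `"both"`; a
#'   `"both"` row is a cancer-identity effect, not a tumor marker).
#' @param blocks optional list of blocks, each a list with `features`
#'   (0-based ids), `rho` (within-block correlation, |rho| < 1), and
#'   `cancers` (codes sharing the block, or `"all"`).
#' @param structures optional data.frame with columns `feature`, `cancer`,
#'   `structure` (`"A"`, `"B"`, `"C"`, `"D"`) and `shift`: group-mean layout
#'   over (frozen-normal, frozen-tumor, FFPE-tumor); see [structured_obf()].
#' @param genes optional list describing the expression stage: `n_null`
#'   (independent genes), `coupled` (data.frame with `target_type`
#'   (`"factor"` block index or `"feature"` id), `target`, `r` target
#'   correlation), `n_lowsd` (genes with sd below the integration filter),
#'   `n_zero` (zero-inflated genes).
#' @param paired_patients if `TRUE`, tumor and normal slides of a cancer
#'   share patients where group sizes allow (TCGA-like); if `FALSE` every
#'   patient contributes slides of a single class, which keeps stratified
#'   patient-level splits exactly class-balanced.
#' @param slides_per_patient maximum slides per patient within a group.
#' @param seed integer master seed; fully determines all output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cancers = 2, cancers = NULL,
                             slides_per_group = c(tumor_frozen = 30,
                                                  normal_frozen = 30),
                             tiles_per_slide = c(10, 30), M = 50,
                             tile_sd = 0.3, markers = NULL, blocks = NULL,
                             structures = NULL, genes = NULL,
                             paired_patients = FALSE,
                             slides_per_patient = 1, seed = 1) {
  if (is.null(cancers)) cancers <- sprintf("C%02d", seq_len(n_cancers))
  allowed <- c("tumor_frozen", "normal_frozen", "tumor_FFPE", "normal_FFPE")
  if (!all(names(slides_per_group) %in% allowed))
    stop("slides_per_group names must be among: ",
         paste(allowed, collapse = ", "))
  stopifnot(all(slides_per_group >= 0), length(tiles_per_slide) == 2,
            tiles_per_slide[1] >= 1, M >= 1, tile_sd >= 0,
            slides_per_patient >= 1)
  if (!is.null(blocks)) {
    for (b in blocks) {
      if (abs(b$rho) >= 1) stop("block correlation must satisfy |rho| < 1")
      if (b$rho < 0)
        stop("negative within-block correlation of an equicorrelated block ",
             "is not positive definite for block size > 1/(1-rho)")
    }
  }
  if (!is.null(markers)) {
    if (!is.null(markers$var_ratio) && any(markers$var_ratio <= 0))
      stop("marker variance ratios must be positive")
  }
  structure(list(cancers = cancers, slides_per_group = slides_per_group,
                 tiles_per_slide = tiles_per_slide, M = M, tile_sd = tile_sd,
                 markers = markers, blocks = blocks, structures = structures,
                 genes = genes, paired_patients = paired_patients,
                 slides_per_patient = slides_per_patient,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Mean shift realizing a target a(m)
#'
#' With equal unit class-conditional variances and a between-class mean
#' shift `delta`, the expected total sample variance is
#' `1 + delta^2 n0 n1 / (n (n - 1))`, so the a(m) ratio has expectation
#' approximately `a`; inverting gives the shift that realizes a requested
#' effect size.
#'
#' @param a target a(m) (> 1).
#' @param n0,n1 class sample sizes.
#' @return the mean shift `delta` in within-class sd units.
#' @export
am_to_delta <- function(a, n0, n1) {
  stopifnot(a > 1, n0 >= 2, n1 >= 2)
  n <- n0 + n1
  sqrt((a - 1) * (n - 1) * n / (n0 * n1))
}

group_key <- function(lesion, preparation) paste(lesion, preparation, sep = "_")

# structure -> group mean layout over (FN, FT, PT); shift scales the layout
structure_means <- function(structure, shift) {
  switch(structure,
         A = c(FN = 0, FT = 0, PT = 0),
         B = c(FN = 0, FT = 0, PT = shift),
         C = c(FN = 0, FT = shift, PT = shift),
         D = c(FN = 0, FT = shift, PT = 0),
         stop("unknown structure: ", structure))
}

#' Generate a synthetic tile-level cohort with ground truth
#'
#' @param config a [generator_config()].
#' @return list with `tiles` (tile feature table), `meta` ([slide_meta()]),
#'   and `truth` (ground-truth marker table, block membership, structure
#'   labels, and per-slide latent factor values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  meta <- build_meta(config)
  n_slides <- nrow(meta)
  M <- config$M
  feat <- as.character(seq_len(M) - 1L)

  # latent factors, one column per block
  n_blocks <- length(config$blocks)
  factors <- if (n_blocks > 0)
    matrix(stats::rnorm(n_slides * n_blocks), n_slides, n_blocks,
           dimnames = list(meta$slide_id, paste0("block", seq_len(n_blocks))))
  else matrix(0, n_slides, 0, dimnames = list(meta$slide_id, NULL))

  z <- matrix(stats::rnorm(n_slides * M), n_slides, M,
              dimnames = list(meta$slide_id, feat))

  # block structure: replace member features with factor model within the
  # block's cancers
  if (n_blocks > 0) for (b in seq_len(n_blocks)) {
    blk <- config$blocks[[b]]
    rows <- if (identical(blk$cancers, "all")) seq_len(n_slides)
            else which(meta$cancer_type %in% blk$cancers)
    cols <- as.character(blk$features)
    z[rows, cols] <- sqrt(blk$rho) * factors[rows, b] +
      sqrt(1 - blk$rho) * z[rows, cols]
  }

  # marker effects: tumor mean shift and variance scaling
  markers <- normalize_markers(config, meta)
  if (!is.null(markers) && nrow(markers) > 0) for (i in seq_len(nrow(markers))) {
    mk <- markers[i, ]
    rows <- if (mk$lesion == "both") which(meta$cancer_type == mk$cancer)
            else which(meta$cancer_type == mk$cancer & meta$lesion == mk$lesion)
    col <- as.character(mk$feature)
    z[rows, col] <- z[rows, col] * sqrt(mk$var_ratio) + mk$delta
  }

  # structured frozen/FFPE group effects
  if (!is.null(config$structures)) for (i in seq_len(nrow(config$structures))) {
    st <- config$structures[i, ]
    mu <- structure_means(st$structure, st$shift)
    col <- as.character(st$feature)
    grp <- ifelse(meta$lesion == "normal" & meta$preparation == "frozen", "FN",
           ifelse(meta$lesion == "tumor" & meta$preparation == "frozen", "FT",
           ifelse(meta$lesion == "tumor" & meta$preparation == "FFPE", "PT",
                  NA)))
    rows <- which(meta$cancer_type == st$cancer & !is.na(grp))
    z[rows, col] <- z[rows, col] + mu[grp[rows]]
  }

  # tile table: slide value + independent tile noise
  n_tiles <- sample(seq(config$tiles_per_slide[1], config$tiles_per_slide[2]),
                    n_slides, replace = TRUE)
  total <- sum(n_tiles)
  tiles <- data.frame(slide_id = rep(meta$slide_id, n_tiles),
                      tile_index = unlist(lapply(n_tiles, seq_len)) - 1L,
                      stringsAsFactors = FALSE)
  noise <- matrix(stats::rnorm(total * M, sd = config$tile_sd), total, M)
  tmat <- z[rep(seq_len(n_slides), n_tiles), , drop = FALSE] + noise
  colnames(tmat) <- paste0("f", seq_len(M) - 1L)
  tiles <- cbind(tiles, as.data.frame(tmat))

  truth <- list(markers = markers, blocks = config$blocks,
                structures = config$structures, factors = factors,
                slide_values = z, config = config)
  list(tiles = tiles, meta = meta, truth = truth)
}

build_meta <- function(config) {
  sid <- pid <- ct <- les <- prep <- character(0)
  for (cc in seq_along(config$cancers)) {
    cancer <- config$cancers[cc]
    patient_counter <- 0L
    normal_pool <- character(0)
    for (g in names(config$slides_per_group)) {
      ng <- config$slides_per_group[[g]]
      if (ng == 0) next
      parts <- strsplit(g, "_", fixed = TRUE)[[1]]
      lesion <- parts[1]; preparation <- parts[2]
      n_pat <- ceiling(ng / config$slides_per_patient)
      pats <- sprintf("%s-PT%03d", cancer, patient_counter + seq_len(n_pat))
      patient_counter <- patient_counter + n_pat
      owner <- rep(pats, each = config$slides_per_patient)[seq_len(ng)]
      if (config$paired_patients && lesion == "normal" &&
          length(normal_pool) > 0) {
        reuse <- seq_len(min(ng, length(normal_pool)))
        owner[reuse] <- normal_pool[reuse]
      }
      if (lesion == "tumor") normal_pool <- unique(c(normal_pool, owner))
      sample_code <- if (lesion == "tumor") "01A" else "11A"
      prep_code <- if (preparation == "frozen") "TS" else "DX"
      ids <- sprintf("%s-%s-%s%03d", owner, sample_code, prep_code,
                     seq_len(ng))
      sid <- c(sid, ids); pid <- c(pid, owner)
      ct <- c(ct, rep(cancer, ng)); les <- c(les, rep(lesion, ng))
      prep <- c(prep, rep(preparation, ng))
    }
  }
  slide_meta(sid, pid, ct, les, prep)
}

normalize_markers <- function(config, meta) {
  mk <- config$markers
  if (is.null(mk) || nrow(mk) == 0) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(mk))) {
    row <- mk[i, , drop = FALSE]
    targets <- if (identical(row$cancer, "all")) config$cancers else row$cancer
    for (cancer in targets) {
      n0 <- sum(meta$cancer_type == cancer & meta$lesion == "normal")
      n1 <- sum(meta$cancer_type == cancer & meta$lesion == "tumor")
      delta <- if (!is.null(row$delta) && !is.na(row$delta)) row$delta
               else am_to_delta(row$target_am, n0, n1)
      vr <- if (!is.null(row$var_ratio) && !is.na(row$var_ratio))
        row$var_ratio else 1
      les <- if (!is.null(row$lesion) && !is.na(row$lesion)) row$lesion
             else "tumor"
      out <- rbind(out, data.frame(cancer = cancer, feature = row$feature,
                                   delta = delta, var_ratio = vr,
                                   lesion = les, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Generate expression profiles coupled to the cohort
#'
#' One profile per distinct vial. Coupled genes are built as
#' `r * standardized(signal) + sqrt(1 - r^2) * noise` around a baseline mean
#' so the realized Pearson correlation with the latent factor (or feature
#' slide value) targets `r`. Null genes are independent Gaussians; a
#' configurable number of low-sd and zero-inflated genes exercise the
#' integration filters.
#'
#' @param truth,meta output of [generate_cohort()].
#' @param config the same [generator_config()]; its `genes` entry drives
#'   this stage (a default of 50 null genes is used when absent).
#' @return an [expression_matrix()] keyed by vial; gene-truth coupling map
#'   attached as attribute `coupling`.
#' @export
generate_expression <- function(truth, meta, config) {
  set.seed(config$seed + 1L)
  gspec <- config$genes
  if (is.null(gspec)) gspec <- list(n_null = 50)
  vials <- unique(meta$vial_id)
  nv <- length(vials)
  first_slide <- match(vials, meta$vial_id)
  cols <- list(); coupling <- NULL
  if (!is.null(gspec$coupled) && nrow(gspec$coupled) > 0) {
    for (i in seq_len(nrow(gspec$coupled))) {
      cp <- gspec$coupled[i, ]
      signal <- if (cp$target_type == "factor") {
        truth$factors[first_slide, as.integer(cp$target)]
      } else {
        col <- as.character(cp$target)
        if (!col %in% colnames(truth$slide_values))
          stop("unknown feature id in gene coupling spec: ", cp$target)
        truth$slide_values[first_slide, col]
      }
      s <- as.numeric(scale(signal))
      g <- cp$r * s + sqrt(1 - cp$r^2) * stats::rnorm(nv)
      nm <- if (!is.null(cp$gene)) as.character(cp$gene) else
        sprintf("COUPLED%03d", i)
      cols[[nm]] <- 3 + g
      coupling <- rbind(coupling,
                        data.frame(gene = nm, target_type = cp$target_type,
                                   target = cp$target, r = cp$r,
                                   stringsAsFactors = FALSE))
    }
  }
  n_null <- if (is.null(gspec$n_null)) 0 else gspec$n_null
  if (n_null > 0) {
    mu <- stats::runif(n_null, 1, 6)
    for (i in seq_len(n_null))
      cols[[sprintf("NULL%04d", i)]] <- stats::rnorm(nv, mu[i], 1)
  }
  n_lowsd <- if (is.null(gspec$n_lowsd)) 0 else gspec$n_lowsd
  if (n_lowsd > 0) for (i in seq_len(n_lowsd))
    cols[[sprintf("LOWSD%03d", i)]] <- stats::rnorm(nv, 2, 0.05)
  n_zero <- if (is.null(gspec$n_zero)) 0 else gspec$n_zero
  if (n_zero > 0) for (i in seq_len(n_zero)) {
    v <- ifelse(stats::runif(nv) < 0.7, 0, stats::rnorm(nv, 2, 1))
    cols[[sprintf("ZERO%03d", i)]] <- v
  }
  if (length(cols) == 0) stop("gene spec produced no genes")
  vals <- do.call(cbind, cols)
  expr <- expression_matrix(vals, vials, names(cols))
  attr(expr, "coupling") <- coupling
  expr
}

#' Generate a per-slide covariate coupled to a feature or factor
#'
#' @param truth,meta output of [generate_cohort()].
#' @param target_type `"factor"` (block index) or `"feature"` (0-based id).
#' @param target block index or feature id.
#' @param r target correlation with the signal.
#' @param name covariate name.
#' @param seed integer seed.
#' @return data.frame with `slide_id`, `value`, and attribute `name`.
#' @export
generate_covariate <- function(truth, meta, target_type = "feature",
                               target = 0, r = 0.5, name = "covariate",
                               seed = 1) {
  set.seed(seed)
  signal <- if (target_type == "factor")
    truth$factors[, as.integer(target)]
  else truth$slide_values[, as.character(target)]
  s <- as.numeric(scale(signal))
  v <- r * s + sqrt(1 - r^2) * stats::rnorm(nrow(meta))
  out <- data.frame(slide_id = meta$slide_id, value = v,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  out
}
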