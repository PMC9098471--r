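#' Training configuration for the patch classifier
#'
#' Two strategies reproduce the mechanism of comparing transfer learning
#' with training from scratch on a tiny practice-sized dataset:
#' `"frozen_features"` passes each patch through a fixed (seed-determined)
#' random convolutional feature map over the luminance channel and trains
#' only a multinomial logistic head on top — the features never change
#' during training, and their colour-blindness mirrors the domain mismatch
#' of a backbone pretrained on unrelated imagery, which is what makes
#' transfer with frozen features weak on stain-dominated classes;
#' `"end_to_end"` trains every parameter of a
#' small single-hidden-layer network on the raw (downsampled) pixels from
#' random initialisation. A custom frozen extractor (e.g. a real pretrained
#' backbone) can be plugged in via `featureFun`.
#'
#' @param strategy `"frozen_features"` or `"end_to_end"`.
#' @param patchSide patch side in pixels at extraction time.
#' @param downSide side the patch is downsampled to before entering the
#'   network (raw-pixel strategy).
#' @param hidden hidden units of the end-to-end network.
#' @param maxit optimisation iterations.
#' @param decay weight decay.
#' @param nFilters,filterSize,poolGrid frozen extractor: number of random
#'   convolution filters, their spatial size, and the side of the average
#'   pooling grid (features = `nFilters * poolGrid^2`).
#' @param augment `"none"` or `"dihedral"` (training split only).
#' @param holdoutFraction fraction of tiles held out for evaluation; the
#'   split holds out whole tiles so that test patches never share a tile
#'   with training patches.
#' @param featureFun optional function `(list of patch arrays) -> matrix`
#'   replacing the default frozen extractor.
#' @param seed integer seed controlling split, initialisation and frozen
#'   filters.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(strategy = c("end_to_end", "frozen_features"),
                        patchSide = 32, downSide = 12, hidden = 12,
                        maxit = 150, decay = 1e-3, nFilters = 6,
                        filterSize = 5, poolGrid = 2,
                        augment = c("none", "dihedral"),
                        holdoutFraction = 0.3, featureFun = NULL, seed = 1) {
  structure(list(strategy = match.arg(strategy), patchSide = patchSide,
                 downSide = downSide, hidden = hidden, maxit = maxit,
                 decay = decay, nFilters = nFilters, filterSize = filterSize,
                 poolGrid = poolGrid, augment = match.arg(augment),
                 holdoutFraction = holdoutFraction, featureFun = featureFun,
                 seed = seed),
            class = "TrainConfig")
}

# Reflect an index vector into [1, n] (mirror padding at the borders).
.reflectIdx <- function(idx, n) {
  idx <- abs(idx - 1L)            # reflect below 1
  m <- 2L * n - 2L
  if (n > 1L) idx <- idx %% m
  idx <- ifelse(idx > n - 1L, m - idx, idx)
  idx + 1L
}

#' Extract labelled patches around ground-truth dots
#'
#' Cuts one square patch per dot, centred on the dot's pixel, labelled with
#' the dot's class. Patches reaching past the tile border are padded by
#' reflection so every patch has the same side.
#'
#' @param tiles named list mapping `image_id` to an RGB raster
#'   (height x width x 3 array), e.g. from [renderImage()].
#' @param gt ground-truth [AnnotationSet()] over those images.
#' @param patchSide patch side in pixels.
#' @return A `PatchDataset`: list with `patches` (list of side x side x 3
#'   arrays), `labels` (character classes) and `provenance` (source image
#'   and centre per patch).
#' @export
extractPatches <- function(tiles, gt, patchSide = 32) {
  stopifnot(is(gt, "AnnotationSet"))
  a <- annotations(gt)
  if (!nrow(a)) stop("empty annotation set: no patches to extract", call. = FALSE)
  missing <- setdiff(unique(a$image_id), names(tiles))
  if (length(missing))
    stop("no tile raster for image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- as.integer(patchSide)
  half <- s %/% 2L
  patches <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    img <- tiles[[a$image_id[i]]]
    h <- dim(img)[1]; w <- dim(img)[2]
    cx <- floor(a$x[i]) + 1L; cy <- floor(a$y[i]) + 1L
    cols <- .reflectIdx((cx - half + 1L):(cx - half + s), w)
    rows <- .reflectIdx((cy - half + 1L):(cy - half + s), h)
    patches[[i]] <- img[rows, cols, , drop = FALSE]
  }
  structure(list(patches = patches, labels = a$cell_class,
                 provenance = data.frame(image_id = a$image_id,
                                         x = a$x, y = a$y)),
            class = "PatchDataset")
}

# The 8 symmetries of the square: 4 rotations x optional horizontal flip.
.dihedral <- function(p, k) {
  if (k >= 4L) p <- p[, dim(p)[2]:1, , drop = FALSE]  # flip
  for (r in seq_len(k %% 4L))                         # rotate 90 deg
    p <- aperm(p, c(2, 1, 3))[dim(p)[2]:1, , , drop = FALSE]
  p
}

#' Augment a patch dataset by the symmetries of the square
#'
#' Deterministically expands each patch into its 8 dihedral variants
#' (rotations by multiples of 90 degrees, with and without flip), the
#' standard flip/rotation augmentation for small image datasets. Labels and
#' provenance are carried over unchanged, so the class histogram scales
#' exactly 8-fold.
#'
#' @param dataset a `PatchDataset` from [extractPatches()].
#' @return The expanded `PatchDataset` (8x the patches).
#' @export
augmentPatches <- function(dataset) {
  stopifnot(inherits(dataset, "PatchDataset"))
  n <- length(dataset$patches)
  out <- vector("list", 8L * n)
  for (i in seq_len(n))
    for (k in 0:7)
      out[[(i - 1L) * 8L + k + 1L]] <- .dihedral(dataset$patches[[i]], k)
  structure(list(patches = out,
                 labels = rep(dataset$labels, each = 8L),
                 provenance = dataset$provenance[rep(seq_len(n), each = 8L), ,
                                                 drop = FALSE]),
            class = "PatchDataset")
}

# Nearest-neighbour downsample of one patch to side x side, flattened.
.downsampleFlat <- function(p, side) {
  idxR <- ceiling(seq_len(side) * dim(p)[1] / side)
  idxC <- ceiling(seq_len(side) * dim(p)[2] / side)
  as.vector(p[idxR, idxC, , drop = FALSE])
}

.pixelMatrix <- function(dataset, side) {
  t(vapply(dataset$patches, .downsampleFlat, numeric(side * side * 3),
           side = side))
}

# Frozen random convolutional feature map: nFilters random filters applied
# to the luminance channel, ReLU, average pooling on a poolGrid x poolGrid
# grid. The filters are a pure function of the seed and are never updated.
# Operating on luminance (not colour) emulates the defining weakness of a
# frozen backbone trained for another domain: its features are not adapted
# to the signal that matters here (stain colourimetry), only to generic
# intensity structure.
.randomFilters <- function(config) {
  f <- config$filterSize
  withSeed(config$seed + 7L,
           matrix(rnorm(f * f * config$nFilters, 0, 1 / f),
                  f * f, config$nFilters))
}

.convFeatures <- function(dataset, config, filters) {
  f <- config$filterSize
  g <- config$poolGrid
  t(vapply(dataset$patches, function(p) {
    lum <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    h <- dim(lum)[1]; w <- dim(lum)[2]
    oh <- h - f + 1L; ow <- w - f + 1L
    im2col <- matrix(0, oh * ow, f * f)
    t <- 0L
    for (dc in 0:(f - 1L))
      for (dr in 0:(f - 1L)) {
        t <- t + 1L
        im2col[, t] <- as.vector(lum[(1L + dr):(oh + dr), (1L + dc):(ow + dc)])
      }
    act <- pmax(im2col %*% filters, 0)  # ReLU
    # pool each filter map on a g x g grid of cells
    rIdx <- ceiling(seq_len(oh) * g / oh)
    cIdx <- ceiling(seq_len(ow) * g / ow)
    cell <- (rep(cIdx, each = oh) - 1L) * g + rep(rIdx, times = ow)
    pooled <- apply(act, 2, function(m) tapply(m, cell, mean))
    as.vector(pooled)
  }, numeric(config$poolGrid^2 * config$nFilters)))
}

# Order-independent fingerprint of a weight set, for freeze verification.
.paramChecksum <- function(w) sprintf("%.12e/%.12e", sum(w), sum(w * w))

# Split tiles (not patches) into train/test so evaluation patches never
# share a tile with training patches.
.tileSplit <- function(dataset, config) {
  tiles <- unique(dataset$provenance$image_id)
  nTest <- max(1L, round(config$holdoutFraction * length(tiles)))
  if (nTest >= length(tiles))
    stop("holdout would consume every tile", call. = FALSE)
  testTiles <- withSeed(config$seed + 11L, sample(tiles, nTest))
  test <- dataset$provenance$image_id %in% testTiles
  list(train = which(!test), test = which(test))
}

.subsetPatches <- function(dataset, idx) {
  structure(list(patches = dataset$patches[idx],
                 labels = dataset$labels[idx],
                 provenance = dataset$provenance[idx, , drop = FALSE]),
            class = "PatchDataset")
}

#' Train a 4-class patch classifier
#'
#' Trains under the strategy in `config` (see [trainConfig()]) on a
#' whole-tile train/holdout split and reports per-class F1 on the held-out
#' patches, computed with the same count-based formulas as the
#' dot-annotation metrics (here FP/FN arise from label disagreement rather
#' than spatial matching). Deterministic for a fixed seed.
#'
#' @param dataset a `PatchDataset` from [extractPatches()].
#' @param config a [trainConfig()].
#' @return A list of class `PatchClassifier` with elements `report`
#'   (per-class + macro F1, 4x4 confusion, training metadata including
#'   frozen-parameter checksums before and after training) and `predict`, a
#'   function mapping a `PatchDataset` to class labels.
#' @export
trainPatchClassifier <- function(dataset, config = trainConfig()) {
  stopifnot(inherits(dataset, "PatchDataset"), inherits(config, "TrainConfig"))
  if (length(unique(dataset$labels)) < 2)
    stop("training needs at least two classes in the dataset", call. = FALSE)
  split <- .tileSplit(dataset, config)
  train <- .subsetPatches(dataset, split$train)
  test <- .subsetPatches(dataset, split$test)
  if (length(unique(train$labels)) < 2)
    stop("training split has a single class; use more tiles", call. = FALSE)
  if (config$augment == "dihedral") train <- augmentPatches(train)
  classes <- cellClasses()
  yTrain <- factor(train$labels, levels = classes)

  if (config$strategy == "frozen_features") {
    featureFun <- config$featureFun
    if (is.null(featureFun)) {
      filters <- .randomFilters(config)
      featureFun <- function(ds) .convFeatures(ds, config, filters)
      frozenBefore <- .paramChecksum(filters)
    } else frozenBefore <- filters <- NULL
    xTrain <- featureFun(train)
    df <- data.frame(y = yTrain, xTrain)
    fit <- withSeed(config$seed,
                    nnet::multinom(y ~ ., df, trace = FALSE,
                                   maxit = config$maxit, decay = config$decay,
                                   MaxNWts = 1e5))
    frozenAfter <- if (!is.null(filters)) .paramChecksum(filters) else NULL
    predictFun <- function(ds) {
      xs <- as.data.frame(featureFun(ds))
      names(xs) <- names(df)[-1]
      as.character(predict(fit, xs))
    }
    trained <- "classification head only (multinomial logistic)"
  } else {
    xTrain <- .pixelMatrix(train, config$downSide)
    yInd <- nnet::class.ind(yTrain)
    fit <- withSeed(config$seed,
                    nnet::nnet(xTrain, yInd, size = config$hidden,
                               softmax = TRUE, decay = config$decay,
                               maxit = config$maxit, MaxNWts = 1e6,
                               trace = FALSE))
    frozenBefore <- frozenAfter <- NULL
    predictFun <- function(ds) {
      xs <- .pixelMatrix(ds, config$downSide)
      colnames(xs) <- NULL
      classes[max.col(predict(fit, xs))]
    }
    trained <- "all parameters (single-hidden-layer network on raw pixels)"
  }

  predTest <- predictFun(test)
  report <- .classifierReport(test$labels, predTest, classes)
  report$metadata <- list(
    strategy = config$strategy, seed = config$seed,
    n_train = length(train$labels), n_test = length(test$labels),
    test_tiles = unique(test$provenance$image_id),
    trained = trained,
    frozen_checksum_before = frozenBefore,
    frozen_checksum_after = frozenAfter)
  structure(list(report = report, predict = predictFun, config = config),
            class = "PatchClassifier")
}

# Per-class metrics from a label contingency, through the same count-based
# derivation as the spatial metrics.
.classifierReport <- function(truth, pred, classes = cellClasses()) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- unclass(table(truth = truth, predicted = pred))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  perClass <- classMetricsFromCounts(classes, tp, fp, fn)
  macro <- mean(perClass$F1, na.rm = TRUE)
  list(per_class = perClass, macro_f1 = macro, confusion = cm)
}

#' Compare frozen-feature and end-to-end training
#'
#' Trains both strategies on the same dataset over paired seeds (identical
#' tile splits within a pair) and summarises per-class and macro F1 with
#' mean and standard deviation, flagging the winning strategy per class.
#'
#' @param dataset a `PatchDataset`.
#' @param seeds integer seeds; each seed trains both strategies.
#' @param baseConfig a [trainConfig()] supplying all non-strategy settings.
#' @return list with `runs` (long data.frame: seed, strategy, class, F1),
#'   `summary` (mean/sd per strategy and class, including `MACRO`), and
#'   `winner` (named character: which strategy has the higher mean F1 per
#'   class).
#' @export
compareStrategies <- function(dataset, seeds = 1:5, baseConfig = trainConfig()) {
  runs <- list()
  for (s in seeds) {
    for (strat in c("frozen_features", "end_to_end")) {
      cfg <- baseConfig
      cfg$strategy <- strat
      cfg$seed <- s
      rep <- trainPatchClassifier(dataset, cfg)$report
      runs[[length(runs) + 1L]] <- rbind(
        data.frame(seed = s, strategy = strat,
                   cell_class = rep$per_class$cell_class,
                   F1 = rep$per_class$F1),
        data.frame(seed = s, strategy = strat, cell_class = "MACRO",
                   F1 = rep$macro_f1))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- aggregate(F1 ~ strategy + cell_class, runs,
                   function(v) c(mean = mean(v, na.rm = TRUE),
                                 sd = stats::sd(v, na.rm = TRUE)),
                   na.action = stats::na.pass)
  summary <- data.frame(strategy = agg$strategy, cell_class = agg$cell_class,
                        mean_f1 = agg$F1[, "mean"], sd_f1 = agg$F1[, "sd"])
  winner <- vapply(unique(summary$cell_class), function(cl) {
    sub <- summary[summary$cell_class == cl, ]
    if (all(is.nan(sub$mean_f1))) return(NA_character_)
    as.character(sub$strategy[which.max(sub$mean_f1)])
  }, character(1))
  list(runs = runs, summary = summary, winner = winner)
}
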