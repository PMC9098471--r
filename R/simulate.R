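#' Layout-generator configuration
#'
#' Controls the synthetic ground-truth generator: tile size, the range of
#' cells per tile, the minimum separation between cell centres and an
#' optional class mix (usually supplied by the level instead). The defaults
#' (8-40 cells per 512 x 512 tile, 30 px minimum separation) keep cell
#' centres more than twice the 14 px matching radius apart so that matching
#' is unambiguous; the crowded preset (`minSeparation = 10`) deliberately
#' stresses the assignment solver.
#'
#' @param width,height tile size in pixels.
#' @param cellsPerImage integer range `c(min, max)` of cells per tile.
#' @param minSeparation minimum Euclidean distance between cell centres.
#' @param classMix optional named class proportions (overridden by a level).
#' @return A list of class `LayoutConfig`.
#' @export
layoutConfig <- function(width = 512, height = 512, cellsPerImage = c(8, 40),
                         minSeparation = 30, classMix = NULL) {
  stopifnot(length(cellsPerImage) == 2, cellsPerImage[1] <= cellsPerImage[2],
            minSeparation >= 0)
  structure(list(width = width, height = height,
                 cellsPerImage = as.integer(cellsPerImage),
                 minSeparation = minSeparation, classMix = classMix),
            class = "LayoutConfig")
}

# Rejection-sample n points in [x0,x1) x [y0,y1) with pairwise separation.
.samplePoints <- function(n, x0, y0, x1, y1, minSep, maxTries = 400L) {
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      cx <- runif(1, x0, x1); cy <- runif(1, y0, y1)
      if (placed == 0L ||
          all((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2 >=
              minSep^2)) {
        placed <- placed + 1L
        xs[placed] <- cx; ys[placed] <- cy
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("cannot place ", n, " cells with separation ", minSep,
           " in the evaluation region (infeasible density)", call. = FALSE)
  }
  list(x = xs, y = ys)
}

#' Generate synthetic ground-truth cell layouts
#'
#' Emulates the competition tiles: each image is a `width` x `height` tile
#' whose annotations live in the central half-size square; cell centres are
#' rejection-sampled in that region honouring the minimum separation, and
#' cell classes are drawn independently from the level's class mix. Fully
#' reproducible from the seed.
#'
#' @param level a [levelConfig()] supplying the class set and mix.
#' @param nImages number of tiles to generate; defaults to the level's
#'   image count.
#' @param layout a [layoutConfig()].
#' @param seed integer seed.
#' @param imagePrefix prefix for generated image ids.
#' @return A ground-truth [AnnotationSet()].
#' @examples
#' lvl <- competitionLevels(defaultCompetition("main"))[["Supercharger"]]
#' gt <- generateLayout(lvl, nImages = 2, seed = 1)
#' table(annotations(gt)$cell_class)
#' @export
generateLayout <- function(level, nImages = NULL, layout = layoutConfig(),
                           seed = 1, imagePrefix = NULL) {
  stopifnot(is(level, "LevelConfig"))
  if (is.null(nImages)) nImages <- level@nImages
  if (is.null(imagePrefix)) imagePrefix <- paste0(tolower(levelName(level)), "_")
  mix <- if (!is.null(layout$classMix)) layout$classMix else level@classMix
  ids <- if (nImages > 0) sprintf("%s%03d", imagePrefix, seq_len(nImages))
         else character()
  images <- imageRecords(ids, layout$width, layout$height, level = levelName(level))
  withSeed(seed, {
    rows <- lapply(seq_len(nImages), function(k) {
      rng <- seq(layout$cellsPerImage[1], layout$cellsPerImage[2])
      n <- if (length(rng) == 1L) rng else sample(rng, 1)
      pts <- .samplePoints(n, images$region_xmin[k], images$region_ymin[k],
                           images$region_xmax[k], images$region_ymax[k],
                           layout$minSeparation)
      data.frame(image_id = ids[k], x = pts$x, y = pts$y,
                 cell_class = sample(names(mix), n, replace = TRUE, prob = mix),
                 annotator_id = "GT")
    })
    ann <- if (length(rows)) do.call(rbind, rows) else
      data.frame(image_id = character(), x = numeric(), y = numeric(),
                 cell_class = character(), annotator_id = character())
    AnnotationSet(ann, images, role = "ground_truth")
  })
}

#' Simulate an annotator over a ground-truth layout
#'
#' Applies an [annotatorProfile()] generatively: each ground-truth cell is
#' detected with the class's detection probability; detected dots are
#' displaced by isotropic Gaussian jitter (clamped to the image), relabelled
#' according to the confusion row of their true class, and a Poisson number
#' of spurious dots per image is added uniformly in the evaluation region
#' with classes from the spurious mix.
#'
#' @param gt ground-truth [AnnotationSet()].
#' @param profile an [annotatorProfile()].
#' @param seed integer seed.
#' @param annotatorId id recorded on the simulated dots.
#' @return A submission [AnnotationSet()] over the same images.
#' @export
simulateAnnotator <- function(gt, profile, seed = 1, annotatorId = "sim") {
  stopifnot(is(gt, "AnnotationSet"), is(profile, "AnnotatorProfile"))
  validObject(profile)
  a <- annotations(gt)
  im <- imageTable(gt)
  withSeed(seed, {
    detected <- runif(nrow(a)) < profile@detectProb[a$cell_class]
    d <- a[detected, , drop = FALSE]
    if (nrow(d)) {
      d$x <- d$x + rnorm(nrow(d), 0, profile@jitterSigma)
      d$y <- d$y + rnorm(nrow(d), 0, profile@jitterSigma)
      idx <- match(d$image_id, im$image_id)
      d$x <- pmin(pmax(d$x, 0), im$width[idx] - 1e-6)
      d$y <- pmin(pmax(d$y, 0), im$height[idx] - 1e-6)
      d$cell_class <- vapply(d$cell_class, function(cl)
        sample(cellClasses(), 1, prob = profile@confusion[cl, ]), character(1))
    }
    spur <- lapply(seq_len(nrow(im)), function(k) {
      ns <- rpois(1, profile@spuriousRate)
      if (!ns) return(NULL)
      data.frame(image_id = im$image_id[k],
                 x = runif(ns, im$region_xmin[k], im$region_xmax[k]),
                 y = runif(ns, im$region_ymin[k], im$region_ymax[k]),
                 cell_class = sample(cellClasses(), ns, replace = TRUE,
                                     prob = profile@spuriousClassMix),
                 annotator_id = annotatorId)
    })
    d$annotator_id <- rep_len(annotatorId, nrow(d))
    ann <- do.call(rbind, c(list(d), spur, list(make.row.names = FALSE)))
    AnnotationSet(ann, im, role = "submission")
  })
}

#' Recover an annotator profile from a submission
#'
#' Inverts the generative model of [simulateAnnotator()] from observed data:
#' dots are matched class-agnostically, then per-class detection
#' probabilities are the class-wise spatial recall, the jitter scale is
#' estimated from the paired-distance distribution (for isotropic Gaussian
#' jitter the paired distance is Rayleigh, so
#' `sigma-hat = mean(distance) / sqrt(pi/2)`), confusion rows are the
#' row-normalised class cross-tabulation of matched pairs, and the spurious
#' rate is the mean number of unmatched submitted dots per image.
#'
#' Two known biases are handled. First, the sigma estimator is truncated at
#' the matching radius: jittered dots landing beyond the radius are lost as
#' misses, so for sigma approaching the radius the estimate is biased low
#' (and detection probability with it). With fewer than 10 matched pairs
#' the sigma estimate is flagged unreliable. Second, a spurious dot that
#' happens to land within the radius of a missed cell is absorbed into a
#' pair, deflating the spurious-rate estimate and inflating recall; the raw
#' moment estimates are corrected for this chance coincidence using the
#' expected absorption probability (missed cells per image times the ratio
#' of the matching disc to the evaluation region), solved by fixed-point
#' iteration. Contamination of the confusion rows and the sigma estimate by
#' absorbed pairs is second order (below one percent under realistic
#' profiles) and is left uncorrected.
#'
#' @param gt ground-truth [AnnotationSet()].
#' @param submission an annotator's [AnnotationSet()].
#' @param config a [matchConfig()]; class-agnostic matching is used
#'   regardless of `classAware`.
#' @return An `AnnotatorProfileEstimate`: an [annotatorProfile()] whose
#'   slots hold the estimates, plus `nPairs`, `nImages` and
#'   `sigmaReliable` diagnostics. Confusion rows for classes never matched
#'   fall back to the identity row.
#' @export
recoverProfile <- function(gt, submission, config = matchConfig()) {
  cfg <- matchConfig(config@radius, config@resolution, classAware = FALSE)
  per <- .matchSets(gt, submission, cfg)
  k <- cellClasses()
  gtCount <- setNames(rep(0, 4), k); hit <- setNames(rep(0, 4), k)
  conf <- matrix(0, 4, 4, dimnames = list(k, k))
  dists <- numeric(); nSpur <- 0
  for (u in per) {
    mp <- matchedPairs(u$match)
    tg <- table(factor(u$gt$cell_class, levels = k))
    gtCount <- gtCount + as.numeric(tg)
    if (nrow(mp)) {
      th <- table(factor(u$gt$cell_class[mp$gt], levels = k))
      hit <- hit + as.numeric(th)
      conf <- conf + unclass(table(factor(u$gt$cell_class[mp$gt], levels = k),
                                   factor(u$pred$cell_class[mp$pred], levels = k)))
      dists <- c(dists, mp$distance)
    }
    nSpur <- nSpur + length(unmatchedPred(u$match))
  }
  nImages <- max(length(per), 1L)
  # chance-coincidence correction: a spurious dot within the matching disc
  # of a missed cell is absorbed into a pair. With M true misses over N
  # images and disc/region area ratio a, each spurious dot is absorbed with
  # probability ~ (M/N) a; the observed unmatched-pred count U and observed
  # miss count therefore understate the truth. Solve S = U / (1 - q),
  # M = M_obs + S q with q = (M/N) a by fixed-point iteration.
  im <- imageTable(gt)
  regionArea <- mean((im$region_xmax - im$region_xmin) *
                     (im$region_ymax - im$region_ymin))
  discRatio <- min(pi * cfg@radius^2 / regionArea, 1)
  mObs <- sum(gtCount) - sum(hit)
  mTrue <- mObs
  S <- nSpur
  for (it in 1:10) {
    q <- min(mTrue / nImages * discRatio, 0.9)
    S <- nSpur / (1 - q)
    mTrue <- mObs + S * q
  }
  absorbed <- S - nSpur
  # absorbed fake pairs count as hits, spread over classes like the misses
  missByClass <- gtCount - hit
  fakeHits <- if (mObs > 0) absorbed * missByClass / mObs else rep(0, 4)
  detect <- ifelse(gtCount > 0, pmax(hit - fakeHits, 0) / gtCount, NA_real_)
  rs <- rowSums(conf)
  confEst <- diag(4); dimnames(confEst) <- list(k, k)
  for (i in seq_len(4)) if (rs[i] > 0) confEst[i, ] <- conf[i, ] / rs[i]
  sigmaHat <- if (length(dists)) mean(dists) / sqrt(pi / 2) else NA_real_
  spurMix <- setNames(rep(0.25, 4), k)
  new("AnnotatorProfileEstimate",
      detectProb = detect, jitterSigma = sigmaHat, confusion = confEst,
      spuriousRate = S / nImages, spuriousClassMix = spurMix,
      nPairs = length(dists), sigmaReliable = length(dists) >= 10,
      nImages = as.integer(nImages))
}
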