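# Shared fixture builders. Everything is generated in code at test time.

# A tiny single-image annotation set from bare vectors.
makeSet <- function(x, y, cls, image = "t1", annotator = "GT",
                    role = "ground_truth", width = 512, height = 512) {
  AnnotationSet(
    data.frame(image_id = image, x = x, y = y, cell_class = cls,
               annotator_id = annotator),
    imageRecords(unique(image), width = width, height = height),
    role = role)
}

# Random matching instance: up to maxN gt and maxM pred dots in a small
# window so that radius-feasible edges are common.
randomInstance <- function(maxN = 6, maxM = 6, span = 40) {
  n <- sample(0:maxN, 1); m <- sample(0:maxM, 1)
  list(gt = data.frame(x = runif(n, 0, span), y = runif(n, 0, span),
                       cell_class = sample(cellClasses(), n, replace = TRUE)),
       pred = data.frame(x = runif(m, 0, span), y = runif(m, 0, span),
                         cell_class = sample(cellClasses(), m, replace = TRUE)))
}

superchargerLevel <- function() {
  competitionLevels(defaultCompetition("main"))[["Supercharger"]]
}

# Ground truth with a fixed number of cells per image (deterministic size).
fixedLayout <- function(level, nImages, cellsPerImage = 20, seed = 1,
                        minSeparation = 30) {
  generateLayout(level, nImages = nImages,
                 layout = layoutConfig(cellsPerImage = rep(cellsPerImage, 2),
                                       minSeparation = minSeparation),
                 seed = seed)
}

# Small rendered patch dataset reused by classifier tests (built once).
renderedPatchDataset <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lvl <- superchargerLevel()
    gt <- fixedLayout(lvl, nImages = 12, cellsPerImage = 18, seed = 42)
    ids <- imageTable(gt)$image_id
    tiles <- setNames(lapply(seq_along(ids), function(k)
      renderImage(gt, ids[k], seed = 500 + k)$raster), ids)
    cache <<- extractPatches(tiles, gt, patchSide = 32)
    cache
  }
})

# Linearly separable synthetic patches: one dominant colour block per class,
# with distinct luminance levels so even colour-blind features carry signal.
separablePatches <- function(nPerClass = 40, side = 32, seed = 9,
                             nTiles = 10) {
  cols <- list(PT = c(0.80, 0.30, 0.10), NT = c(0.10, 0.20, 0.70),
               PNT = c(0.95, 0.85, 0.20), NNT = c(0.05, 0.05, 0.15))
  set.seed(seed)
  local({
    patches <- list(); labels <- character(); imgid <- character()
    for (cl in names(cols)) {
      for (i in seq_len(nPerClass)) {
        p <- array(rep(cols[[cl]], each = side * side), c(side, side, 3))
        p <- pmin(pmax(p + array(rnorm(side * side * 3, 0, 0.03),
                                 c(side, side, 3)), 0), 1)
        patches[[length(patches) + 1L]] <- p
        labels <- c(labels, cl)
        imgid <- c(imgid, sprintf("tile_%02d", sample.int(nTiles, 1)))
      }
    }
    structure(list(patches = patches, labels = labels,
                   provenance = data.frame(image_id = imgid,
                                           x = 0, y = 0)),
              class = "PatchDataset")
  })
}
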