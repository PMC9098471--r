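#' @import methods
NULL

#' The four Ki67 cell classes
#'
#' Cells on a Ki67-stained tile are labelled as positive tumour (PT),
#' negative tumour (NT), positive non-tumour (PNT) or negative non-tumour
#' (NNT), where "positive" means the nucleus expresses Ki67 and stains brown
#' (DAB) and "negative" nuclei counterstain blue (haematoxylin).
#'
#' @return Character vector of the four canonical class labels, in the order
#'   they are introduced across competition levels.
#' @examples
#' cellClasses()
#' @export
cellClasses <- function() c("PT", "NT", "PNT", "NNT")

# Canonicalise class labels: case-insensitive on read, uppercase canonical.
# Returns NA for labels outside the whitelist.
canonicalClass <- function(x) {
  up <- toupper(trimws(as.character(x)))
  up[!up %in% cellClasses()] <- NA_character_
  up
}

.validAnnotationCols <- c("image_id", "x", "y", "cell_class", "annotator_id")
.validImageCols <- c("image_id", "width", "height", "level",
                     "region_xmin", "region_ymin", "region_xmax", "region_ymax")

#' @rdname AnnotationSet
#' @export
setClass("AnnotationSet",
  representation(
    annotations = "data.frame",
    images = "data.frame",
    role = "character"
  )
)

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  a <- object@annotations
  im <- object@images
  if (!all(.validAnnotationCols %in% names(a)))
    msgs <- c(msgs, paste("annotations must have columns",
                          paste(.validAnnotationCols, collapse = ", ")))
  if (!all(.validImageCols %in% names(im)))
    msgs <- c(msgs, paste("images must have columns",
                          paste(.validImageCols, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (!object@role %in% c("ground_truth", "submission"))
    msgs <- c(msgs, "role must be 'ground_truth' or 'submission'")
  if (anyDuplicated(im$image_id))
    msgs <- c(msgs, "duplicate image_id in image table")
  bad <- !a$image_id %in% im$image_id
  if (any(bad))
    msgs <- c(msgs, paste0("annotations reference unknown images (rows ",
                           paste(utils::head(which(bad), 10), collapse = ", "), ")"))
  badcls <- is.na(canonicalClass(a$cell_class))
  if (any(badcls))
    msgs <- c(msgs, paste0("unknown cell_class (rows ",
                           paste(utils::head(which(badcls), 10), collapse = ", "), ")"))
  if (nrow(a) && !any(bad)) {
    idx <- match(a$image_id, im$image_id)
    out <- a$x < 0 | a$y < 0 | a$x >= im$width[idx] | a$y >= im$height[idx]
    if (any(out))
      msgs <- c(msgs, paste0("annotation coordinates outside image bounds (rows ",
                             paste(utils::head(which(out), 10), collapse = ", "), ")"))
  }
  regbad <- im$region_xmin >= im$region_xmax | im$region_ymin >= im$region_ymax |
    im$region_xmin < 0 | im$region_ymin < 0 |
    im$region_xmax > im$width | im$region_ymax > im$height
  if (any(regbad))
    msgs <- c(msgs, "eval region must be non-empty and lie inside the image")
  if (length(msgs)) msgs else TRUE
})

#' Point-annotation sets
#'
#' An `AnnotationSet` holds dot annotations (one clicked cell per row:
#' image, continuous pixel position, cell class, annotator) together with the
#' table of image tiles they refer to and a role flag distinguishing expert
#' ground truth from participant submissions. Coordinates use the raster
#' convention: origin at the top-left corner, x rightward, y downward,
#' 0-based continuous pixels. Each image carries a half-open evaluation
#' region `[xmin, xmax) x [ymin, ymax)`; by default the central square
#' covering a quarter of the tile area, matching the convention that
#' annotation of a 512 x 512 tile is restricted to its central 256 x 256
#' square.
#'
#' Duplicate dots are legal input (participants may double-click one cell);
#' one-to-one matching at scoring time turns extras into false positives.
#'
#' @param annotations data.frame with columns `image_id`, `x`, `y`,
#'   `cell_class` (case-insensitive; canonicalised to upper case) and
#'   optionally `annotator_id` (defaults to `"GT"` for ground truth).
#' @param images data.frame of image records, from [imageRecords()].
#' @param role `"ground_truth"` or `"submission"`.
#' @return An `AnnotationSet` object.
#' @seealso [imageRecords()], [readAnnotations()], [filterToRegion()]
#' @examples
#' im <- imageRecords("tile_1")
#' ann <- data.frame(image_id = "tile_1", x = 200, y = 180, cell_class = "pt")
#' AnnotationSet(ann, im, role = "ground_truth")
#' @export
AnnotationSet <- function(annotations, images, role = c("ground_truth", "submission")) {
  role <- match.arg(role)
  annotations <- as.data.frame(annotations)
  if (!nrow(annotations)) {
    annotations <- data.frame(image_id = character(), x = numeric(),
                              y = numeric(), cell_class = character(),
                              annotator_id = character())
  }
  if (is.null(annotations$annotator_id))
    annotations$annotator_id <- if (role == "ground_truth") "GT" else "anon"
  cls <- canonicalClass(annotations$cell_class)
  if (anyNA(cls)) {
    bad <- which(is.na(cls))
    stop("unknown cell_class label(s) ",
         paste(sQuote(unique(annotations$cell_class[bad])), collapse = ", "),
         " in rows ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  annotations$cell_class <- cls
  annotations$image_id <- as.character(annotations$image_id)
  annotations$annotator_id <- as.character(annotations$annotator_id)
  annotations$x <- as.numeric(annotations$x)
  annotations$y <- as.numeric(annotations$y)
  annotations <- annotations[.validAnnotationCols]
  rownames(annotations) <- NULL
  new("AnnotationSet", annotations = annotations,
      images = as.data.frame(images), role = role)
}

#' Build an image-record table
#'
#' @param image_id character vector of tile identifiers.
#' @param width,height tile size in pixels.
#' @param level competition level name the tiles belong to.
#' @param region evaluation region as `c(xmin, ymin, xmax, ymax)` in pixels,
#'   half-open on the upper bounds; `NULL` for the default central square
#'   `[w/4, 3w/4) x [h/4, 3h/4)`.
#' @return data.frame with one row per image.
#' @examples
#' imageRecords(c("a", "b"))  # default 512x512 with [128,384) central square
#' @export
imageRecords <- function(image_id, width = 512L, height = 512L,
                         level = NA_character_, region = NULL) {
  n <- length(image_id)
  if (is.null(region))
    region <- c(width / 4, height / 4, 3 * width / 4, 3 * height / 4)
  data.frame(
    image_id = as.character(image_id),
    width = rep_len(as.numeric(width), n),
    height = rep_len(as.numeric(height), n),
    level = rep_len(as.character(level), n),
    region_xmin = rep_len(region[1], n), region_ymin = rep_len(region[2], n),
    region_xmax = rep_len(region[3], n), region_ymax = rep_len(region[4], n)
  )
}

#' Matching configuration
#'
#' A dot is accepted as correctly annotated when it lies within a Euclidean
#' radius of the ground-truth dot: 14 pixels by default, i.e. 3.5 um at the
#' 0.25 um/px resolution of a 40X scan. When `classAware` is `TRUE`
#' (the default, used for accuracy and per-class F1) matching is computed
#' independently within each cell class; the class-agnostic mode is used
#' only to build cross-class confusion matrices.
#'
#' @param radius matching radius in pixels (> 0).
#' @param resolution scan resolution, micrometres per pixel (display only).
#' @param classAware logical; match within class or across classes.
#' @return A `MatchConfig` object.
#' @examples
#' matchConfig()            # 14 px, class-aware
#' radiusMicrons(14, 0.25)  # the same radius in micrometres
#' @export
matchConfig <- function(radius = 14, resolution = 0.25, classAware = TRUE) {
  new("MatchConfig", radius = as.numeric(radius),
      resolution = as.numeric(resolution), classAware = classAware)
}

#' @rdname matchConfig
#' @export
setClass("MatchConfig",
  representation(radius = "numeric", resolution = "numeric", classAware = "logical"))

setValidity("MatchConfig", function(object) {
  if (length(object@radius) != 1 || !is.finite(object@radius) || object@radius <= 0)
    return("radius must be a single positive number")
  if (object@resolution <= 0) return("resolution must be positive")
  TRUE
})

#' @rdname matchPoints
#' @export
setClass("MatchResult",
  representation(
    pairs = "data.frame",      # gt, pred, distance
    unmatchedGT = "integer",
    unmatchedPred = "integer",
    nGT = "integer",
    nPred = "integer",
    radius = "numeric"
  )
)

setValidity("MatchResult", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("gt", "pred", "distance") %in% names(p)))
    return("pairs must have columns gt, pred, distance")
  if (anyDuplicated(p$gt) || anyDuplicated(p$pred))
    msgs <- c(msgs, "matching must be one-to-one")
  if (any(p$distance > object@radius + 1e-9))
    msgs <- c(msgs, "paired distance exceeds the matching radius")
  if (nrow(p) + length(object@unmatchedGT) != object@nGT)
    msgs <- c(msgs, "pairs + unmatched gt must account for every gt dot")
  if (nrow(p) + length(object@unmatchedPred) != object@nPred)
    msgs <- c(msgs, "pairs + unmatched pred must account for every pred dot")
  if (length(intersect(p$gt, object@unmatchedGT)) ||
      length(intersect(p$pred, object@unmatchedPred)))
    msgs <- c(msgs, "a dot cannot be both paired and unmatched")
  if (length(msgs)) msgs else TRUE
})

#' Annotator skill profiles
#'
#' A generative description of one annotator: the probability of detecting
#' (clicking) a cell of each class, isotropic Gaussian localisation jitter
#' around the true position, a row-stochastic class-confusion matrix applied
#' to detected cells, and a Poisson rate of spurious dots per image placed
#' uniformly in the evaluation region (modelling artefacts mis-read as
#' cells).
#'
#' @param detectProb detection probability per class; a single number or a
#'   named vector over [cellClasses()].
#' @param jitterSigma standard deviation of the localisation jitter, pixels.
#' @param confusion 4 x 4 row-stochastic matrix (rows = true class,
#'   columns = recorded class) in [cellClasses()] order, or `NULL` for the
#'   identity (no confusion).
#' @param spuriousRate expected number of spurious dots per image.
#' @param spuriousClassMix class proportions for spurious dots; defaults to
#'   uniform over the four classes.
#' @return An `AnnotatorProfile` object.
#' @examples
#' annotatorProfile(detectProb = 0.8, jitterSigma = 2, spuriousRate = 3)
#' @export
annotatorProfile <- function(detectProb = 1, jitterSigma = 0, confusion = NULL,
                             spuriousRate = 0, spuriousClassMix = NULL) {
  k <- cellClasses()
  if (length(detectProb) == 1)
    detectProb <- setNames(rep(unname(detectProb), 4), k)
  detectProb <- detectProb[k]
  names(detectProb) <- k
  if (is.null(confusion)) confusion <- diag(4)
  confusion <- as.matrix(confusion)
  dimnames(confusion) <- list(k, k)
  if (is.null(spuriousClassMix)) spuriousClassMix <- setNames(rep(0.25, 4), k)
  spuriousClassMix <- spuriousClassMix[k]
  names(spuriousClassMix) <- k
  new("AnnotatorProfile", detectProb = detectProb,
      jitterSigma = as.numeric(jitterSigma), confusion = confusion,
      spuriousRate = as.numeric(spuriousRate),
      spuriousClassMix = spuriousClassMix)
}

# Shared slot layout for generative profiles and their estimates; the
# estimate class tolerates NA where a class was never observed.
setClass("AnnotatorModel",
  representation(
    "VIRTUAL",
    detectProb = "numeric",
    jitterSigma = "numeric",
    confusion = "matrix",
    spuriousRate = "numeric",
    spuriousClassMix = "numeric"
  )
)

#' @rdname annotatorProfile
#' @export
setClass("AnnotatorProfile", contains = "AnnotatorModel")

setValidity("AnnotatorProfile", function(object) {
  msgs <- character()
  if (anyNA(object@detectProb) || any(object@detectProb < 0 | object@detectProb > 1))
    msgs <- c(msgs, "detectProb must be probabilities in [0, 1] for all four classes")
  if (object@jitterSigma < 0) msgs <- c(msgs, "jitterSigma must be >= 0")
  cm <- object@confusion
  if (!all(dim(cm) == c(4, 4)) || anyNA(cm) || any(cm < 0) ||
      any(abs(rowSums(cm) - 1) > 1e-6))
    msgs <- c(msgs, "confusion must be a 4x4 row-stochastic matrix")
  if (object@spuriousRate < 0) msgs <- c(msgs, "spuriousRate must be >= 0")
  if (anyNA(object@spuriousClassMix) || any(object@spuriousClassMix < 0) ||
      abs(sum(object@spuriousClassMix) - 1) > 1e-6)
    msgs <- c(msgs, "spuriousClassMix must sum to 1")
  if (length(msgs)) msgs else TRUE
})

# Profile estimated by recoverProfile(): profile slots plus diagnostics.
# NA marks parameters that were unobservable (e.g. no cells of a class).
#' @rdname recoverProfile
#' @export
setClass("AnnotatorProfileEstimate",
  contains = "AnnotatorModel",
  representation(nPairs = "integer", sigmaReliable = "logical",
                 nImages = "integer")
)

setValidity("AnnotatorProfileEstimate", function(object) {
  if (!all(dim(object@confusion) == c(4, 4)))
    return("confusion estimate must be 4x4")
  if (length(object@detectProb) != 4)
    return("detectProb estimate must cover the four classes")
  TRUE
})

#' Competition level configuration
#'
#' @param name level name (`"Mild"`, `"Hot"`, `"Spicy"`, `"Supercharger"` in
#'   the main edition).
#' @param nImages number of image tiles at the level.
#' @param classes ordered subset of [cellClasses()] annotated at the level.
#' @param classMix named proportions over `classes`, summing to 1.
#' @param passThreshold accuracy (0-100 scale) required to pass; the bound
#'   is inclusive ("at least half of the cells").
#' @return A `LevelConfig` object.
#' @examples
#' levelConfig("Mild", 20, "PT", c(PT = 1))
#' @export
levelConfig <- function(name, nImages, classes, classMix, passThreshold = 50) {
  classMix <- classMix[classes]
  names(classMix) <- classes
  new("LevelConfig", name = as.character(name), nImages = as.integer(nImages),
      classes = as.character(classes), classMix = as.numeric(classMix) |>
        setNames(classes), passThreshold = as.numeric(passThreshold))
}

#' @rdname levelConfig
#' @export
setClass("LevelConfig",
  representation(name = "character", nImages = "integer", classes = "character",
                 classMix = "numeric", passThreshold = "numeric"))

setValidity("LevelConfig", function(object) {
  msgs <- character()
  if (!all(object@classes %in% cellClasses()))
    msgs <- c(msgs, "classes must be a subset of cellClasses()")
  if (anyNA(object@classMix) || any(object@classMix < 0) ||
      abs(sum(object@classMix) - 1) > 1e-6)
    msgs <- c(msgs, "classMix must be non-negative and sum to 1 over the level's classes")
  if (object@nImages < 0) msgs <- c(msgs, "nImages must be >= 0")
  if (object@passThreshold < 0 || object@passThreshold > 100)
    msgs <- c(msgs, "passThreshold must be in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname defaultCompetition
#' @export
setClass("CompetitionConfig",
  representation(edition = "character", levels = "list", practiceLevels = "list"))

setValidity("CompetitionConfig", function(object) {
  ok <- vapply(c(object@levels, object@practiceLevels),
               function(l) is(l, "LevelConfig"), logical(1))
  if (!all(ok)) return("levels must be LevelConfig objects")
  TRUE
})
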