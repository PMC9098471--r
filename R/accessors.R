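#' Accessors for AnnotationSet and friends
#'
#' `annotations()` returns the dot table, `imageTable()` the image records,
#' `annotationRole()` the role flag, `nDots()` the number of dots.
#' `matchedPairs()`, `unmatchedGT()` and `unmatchedPred()` access the parts
#' of a [matchPoints()] result.
#'
#' @param object an `AnnotationSet` or `MatchResult`.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setMethod("annotations", "AnnotationSet", function(object) object@annotations)

#' @rdname accessors
#' @export
setGeneric("imageTable", function(object) standardGeneric("imageTable"))
#' @rdname accessors
#' @export
setMethod("imageTable", "AnnotationSet", function(object) object@images)

#' @rdname accessors
#' @export
setGeneric("annotationRole", function(object) standardGeneric("annotationRole"))
#' @rdname accessors
#' @export
setMethod("annotationRole", "AnnotationSet", function(object) object@role)

#' @rdname accessors
#' @export
setGeneric("nDots", function(object) standardGeneric("nDots"))
#' @rdname accessors
#' @export
setMethod("nDots", "AnnotationSet", function(object) nrow(object@annotations))

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(object) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchResult", function(object) object@pairs)

#' @rdname accessors
#' @export
setGeneric("unmatchedGT", function(object) standardGeneric("unmatchedGT"))
#' @rdname accessors
#' @export
setMethod("unmatchedGT", "MatchResult", function(object) object@unmatchedGT)

#' @rdname accessors
#' @export
setGeneric("unmatchedPred", function(object) standardGeneric("unmatchedPred"))
#' @rdname accessors
#' @export
setMethod("unmatchedPred", "MatchResult", function(object) object@unmatchedPred)

setMethod("show", "AnnotationSet", function(object) {
  cat("AnnotationSet (", object@role, ")\n", sep = "")
  cat("  ", nrow(object@annotations), " dots over ",
      nrow(object@images), " images\n", sep = "")
  tab <- table(factor(object@annotations$cell_class, levels = cellClasses()))
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  annotators:",
      paste(unique(object@annotations$annotator_id), collapse = ", "), "\n")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult: ", nrow(object@pairs), " pairs (radius ", object@radius,
      " px), ", length(object@unmatchedGT), " unmatched gt, ",
      length(object@unmatchedPred), " unmatched pred\n", sep = "")
})

setMethod("show", "MatchConfig", function(object) {
  cat("MatchConfig: radius ", object@radius, " px (",
      radiusMicrons(object@radius, object@resolution), " um), ",
      if (object@classAware) "class-aware" else "class-agnostic", "\n", sep = "")
})

setMethod("show", "AnnotatorModel", function(object) {
  cat("AnnotatorProfile\n")
  cat("  detectProb:", paste(names(object@detectProb),
      sprintf("%.3f", object@detectProb), sep = "=", collapse = " "), "\n")
  cat("  jitterSigma:", object@jitterSigma, "px;  spuriousRate:",
      object@spuriousRate, "/image\n")
  offdiag <- sum(object@confusion) - sum(diag(object@confusion))
  cat("  confusion: ", if (offdiag == 0) "identity" else
      sprintf("%.3f off-diagonal mass per row (mean)", offdiag / 4), "\n", sep = "")
})

setMethod("show", "AnnotatorProfileEstimate", function(object) {
  callNextMethod()
  cat("  estimated from ", object@nPairs, " matched pairs over ",
      object@nImages, " images; sigma estimate ",
      if (object@sigmaReliable) "reliable" else "UNRELIABLE (< 10 pairs)",
      "\n", sep = "")
})

setMethod("show", "LevelConfig", function(object) {
  cat("Level ", object@name, ": ", object@nImages, " images, classes ",
      paste(object@classes, collapse = ","), " (mix ",
      paste(sprintf("%.2f", object@classMix), collapse = "/"),
      "), pass >= ", object@passThreshold, "\n", sep = "")
})

setMethod("show", "CompetitionConfig", function(object) {
  cat("CompetitionConfig: ", object@edition, " edition, ",
      length(object@levels), " competition levels, ",
      length(object@practiceLevels), " practice levels\n", sep = "")
  for (l in object@levels) show(l)
})

#' @rdname levelConfig
#' @param object a `LevelConfig`.
#' @export
setGeneric("levelName", function(object) standardGeneric("levelName"))
#' @rdname levelConfig
#' @export
setMethod("levelName", "LevelConfig", function(object) object@name)

#' @rdname defaultCompetition
#' @param object a `CompetitionConfig`.
#' @export
setGeneric("competitionLevels", function(object) standardGeneric("competitionLevels"))
#' @rdname defaultCompetition
#' @export
setMethod("competitionLevels", "CompetitionConfig", function(object) {
  setNames(object@levels, vapply(object@levels, levelName, character(1)))
})

#' @rdname defaultCompetition
#' @export
setGeneric("practiceLevels", function(object) standardGeneric("practiceLevels"))
#' @rdname defaultCompetition
#' @export
setMethod("practiceLevels", "CompetitionConfig", function(object) {
  setNames(object@practiceLevels,
           vapply(object@practiceLevels, levelName, character(1)))
})

#' @rdname annotatorProfile
#' @param object an `AnnotatorProfile`.
#' @export
setGeneric("detectProb", function(object) standardGeneric("detectProb"))
#' @rdname annotatorProfile
#' @export
setMethod("detectProb", "AnnotatorModel", function(object) object@detectProb)

#' @rdname annotatorProfile
#' @export
setGeneric("jitterSigma", function(object) standardGeneric("jitterSigma"))
#' @rdname annotatorProfile
#' @export
setMethod("jitterSigma", "AnnotatorModel", function(object) object@jitterSigma)

#' @rdname annotatorProfile
#' @export
setGeneric("confusionRows", function(object) standardGeneric("confusionRows"))
#' @rdname annotatorProfile
#' @export
setMethod("confusionRows", "AnnotatorModel", function(object) object@confusion)

#' @rdname annotatorProfile
#' @export
setGeneric("spuriousRate", function(object) standardGeneric("spuriousRate"))
#' @rdname annotatorProfile
#' @export
setMethod("spuriousRate", "AnnotatorModel", function(object) object@spuriousRate)
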