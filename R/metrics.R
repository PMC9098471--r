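# Shared derivation of TPR/PPV/F1 from raw counts. Undefined rates (zero
# denominators) are NA, never silent zeros, and are excluded from averages
# by downstream summaries. Used by both the spatial-matching path and the
# patch-classifier contingency path.
classMetricsFromCounts <- function(cell_class, TP, FP, FN) {
  TPR <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  PPV <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  F1 <- ifelse(!is.na(TPR) & !is.na(PPV) & (TPR + PPV) > 0,
               2 * TPR * PPV / (TPR + PPV), NA_real_)
  data.frame(cell_class = cell_class, TP = as.integer(TP), FP = as.integer(FP),
             FN = as.integer(FN), TPR = TPR, PPV = PPV, F1 = F1)
}

# Match every shared image of a gt/pred AnnotationSet pair, returning a list
# of per-image results together with the annotation rows they index.
.matchSets <- function(gtSet, predSet, config) {
  stopifnot(is(gtSet, "AnnotationSet"), is(predSet, "AnnotationSet"))
  gtA <- annotations(gtSet); prA <- annotations(predSet)
  ids <- unique(imageTable(gtSet)$image_id)
  lapply(ids, function(id) {
    g <- gtA[gtA$image_id == id, , drop = FALSE]
    p <- prA[prA$image_id == id, , drop = FALSE]
    list(image_id = id, gt = g, pred = p,
         match = matchPoints(g, p, config))
  })
}

#' Competition accuracy of a submission
#'
#' The competition statistic: the number of correctly annotated cells
#' divided by the number of all ground-truth cells, times 100. A cell
#' counts as correctly annotated when a dot of the same class lies within
#' the matching radius under the one-to-one assignment of [matchPoints()];
#' with class-aware matching this equals 100 x pooled recall.
#'
#' @param gtSet ground-truth [AnnotationSet()] for one level, filtered to
#'   the evaluation regions.
#' @param predSet one annotator's submission over the same images.
#' @param config a [matchConfig()].
#' @return A list with `n_correct`, `n_total` and `accuracy` on the 0-100
#'   scale.
#' @examples
#' im <- imageRecords("t")
#' gt <- AnnotationSet(data.frame(image_id = "t", x = c(150, 200), y = 150,
#'                                cell_class = "PT"), im)
#' competitionAccuracy(gt, gt, matchConfig())$accuracy  # 100
#' @export
competitionAccuracy <- function(gtSet, predSet, config = matchConfig()) {
  per <- .matchSets(gtSet, predSet, config)
  nTotal <- sum(vapply(per, function(u) nrow(u$gt), integer(1)))
  if (nTotal == 0)
    stop("accuracy is undefined: no ground-truth cells in the evaluated images",
         call. = FALSE)
  nCorrect <- sum(vapply(per, function(u) nrow(matchedPairs(u$match)), integer(1)))
  list(n_correct = nCorrect, n_total = nTotal,
       accuracy = 100 * nCorrect / nTotal)
}

#' Per-class detection metrics
#'
#' For each cell class, counts true positives (matched pairs), false
#' negatives (unmatched ground-truth dots) and false positives (unmatched
#' submitted dots) summed over images, and derives recall
#' (TPR = TP/(TP+FN)), precision (PPV = TP/(TP+FP)) and their harmonic mean
#' F1 = 2.TPR.PPV/(TPR+PPV). A pooled `"ALL"` row sums the raw counts over
#' classes before deriving rates (micro-average). Rates with a zero
#' denominator are `NA` (undefined), never zero.
#'
#' @inheritParams competitionAccuracy
#' @return data.frame with one row per class plus the pooled `ALL` row:
#'   columns `cell_class`, `TP`, `FP`, `FN`, `TPR`, `PPV`, `F1`.
#' @export
perClassMetrics <- function(gtSet, predSet, config = matchConfig()) {
  per <- .matchSets(gtSet, predSet, config)
  classes <- cellClasses()
  counts <- matrix(0L, length(classes), 3,
                   dimnames = list(classes, c("TP", "FP", "FN")))
  for (u in per) {
    mp <- matchedPairs(u$match)
    tp <- table(factor(u$gt$cell_class[mp$gt], levels = classes))
    fn <- table(factor(u$gt$cell_class[unmatchedGT(u$match)], levels = classes))
    fp <- table(factor(u$pred$cell_class[unmatchedPred(u$match)], levels = classes))
    counts[, "TP"] <- counts[, "TP"] + as.integer(tp)
    counts[, "FN"] <- counts[, "FN"] + as.integer(fn)
    counts[, "FP"] <- counts[, "FP"] + as.integer(fp)
  }
  out <- classMetricsFromCounts(classes, counts[, "TP"], counts[, "FP"],
                                counts[, "FN"])
  all <- classMetricsFromCounts("ALL", sum(counts[, "TP"]), sum(counts[, "FP"]),
                                sum(counts[, "FN"]))
  rbind(out, all)
}

#' Cross-class confusion matrix from spatial matching
#'
#' Dots are first matched class-agnostically (radius only), then each pair
#' contributes to the cell (true class, recorded class). Ground-truth dots
#' with no spatial match (missed cells) fall in the `NONE` column; submitted
#' dots with no match (spurious dots) fall in the `NONE` row. Row sums over
#' the class rows therefore equal ground-truth class counts and column sums
#' equal submitted class counts.
#'
#' @inheritParams competitionAccuracy
#' @return 5 x 5 integer matrix, rows = ground truth (`PT`, `NT`, `PNT`,
#'   `NNT`, `NONE`), columns = submission.
#' @export
confusionMatrix <- function(gtSet, predSet, config = matchConfig()) {
  cfg <- matchConfig(config@radius, config@resolution, classAware = FALSE)
  per <- .matchSets(gtSet, predSet, cfg)
  lv <- c(cellClasses(), "NONE")
  cm <- matrix(0L, 5, 5, dimnames = list(truth = lv, submission = lv))
  for (u in per) {
    mp <- matchedPairs(u$match)
    if (nrow(mp)) {
      t3 <- table(factor(u$gt$cell_class[mp$gt], levels = lv),
                  factor(u$pred$cell_class[mp$pred], levels = lv))
      cm <- cm + as.integer(t3)
    }
    miss <- table(factor(u$gt$cell_class[unmatchedGT(u$match)], levels = lv))
    spur <- table(factor(u$pred$cell_class[unmatchedPred(u$match)], levels = lv))
    cm[, "NONE"] <- cm[, "NONE"] + as.integer(miss)
    cm["NONE", ] <- cm["NONE", ] + as.integer(spur)
  }
  cm
}

#' Pool per-image (or per-unit) metric tables
#'
#' Sums raw TP/FP/FN counts across a list of [perClassMetrics()]-shaped
#' tables before deriving rates (micro-average). Pooling counts first is
#' not the same as averaging per-image F1 values; small images with
#' undefined rates contribute their counts rather than being dropped.
#'
#' @param metricsList non-empty list of data.frames with columns
#'   `cell_class`, `TP`, `FP`, `FN`.
#' @return A pooled metrics data.frame in the same shape.
#' @export
aggregateMetrics <- function(metricsList) {
  if (!length(metricsList)) stop("no metrics to aggregate", call. = FALSE)
  all <- do.call(rbind, metricsList)
  keep <- unique(as.character(all$cell_class))
  agg <- lapply(keep, function(cl) {
    sub <- all[all$cell_class == cl, , drop = FALSE]
    classMetricsFromCounts(cl, sum(sub$TP), sum(sub$FP), sum(sub$FN))
  })
  do.call(rbind, agg)
}

#' Distribution of F1 across annotators
#'
#' Summarises, per cell class, the spread of F1 over a cohort of annotators:
#' minimum, lower quartile, mean, median, upper quartile and maximum, with
#' undefined (NA) F1 values excluded and their count reported.
#'
#' @param metricsByAnnotator named list of [perClassMetrics()] tables, one
#'   per annotator.
#' @return data.frame with one row per cell class (plus `ALL`).
#' @export
f1Distribution <- function(metricsByAnnotator) {
  if (!length(metricsByAnnotator)) stop("no annotators", call. = FALSE)
  all <- do.call(rbind, lapply(names(metricsByAnnotator), function(id) {
    m <- metricsByAnnotator[[id]]
    m$annotator_id <- id
    m
  }))
  classes <- unique(as.character(all$cell_class))
  rows <- lapply(classes, function(cl) {
    f1 <- all$F1[all$cell_class == cl]
    def <- f1[!is.na(f1)]
    if (!length(def))
      return(data.frame(cell_class = cl, n = 0L, n_undefined = sum(is.na(f1)),
                        min = NA_real_, q25 = NA_real_, mean = NA_real_,
                        median = NA_real_, q75 = NA_real_, max = NA_real_))
    q <- quantile(def, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cell_class = cl, n = length(def), n_undefined = sum(is.na(f1)),
               min = min(def), q25 = q[1], mean = mean(def), median = q[2],
               q75 = q[3], max = max(def))
  })
  do.call(rbind, rows)
}
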