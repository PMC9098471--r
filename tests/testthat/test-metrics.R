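# Hand-computable contingencies: F1 checked against the closed formulas.
test_that("per-class rates follow the TP/FP/FN formulas exactly", {
  # one image, constructed so PT has TP=3 FP=2 FN=1
  gt <- makeSet(x = c(150, 200, 250, 300), y = 150, cls = "PT")
  pred <- makeSet(x = c(151, 201, 251, 170, 330), y = c(150, 150, 150, 250, 250),
                  cls = "PT", annotator = "a", role = "submission")
  m <- perClassMetrics(gt, pred)
  pt <- m[m$cell_class == "PT", ]
  expect_equal(pt$TP, 3); expect_equal(pt$FP, 2); expect_equal(pt$FN, 1)
  expect_equal(pt$TPR, 0.75)
  expect_equal(pt$PPV, 0.6)
  expect_equal(pt$F1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(pt$F1, 4), 0.6667)
})

test_that("a perfect submission scores accuracy 100 and F1 = 1 everywhere", {
  set.seed(4)
  gt <- fixedLayout(superchargerLevel(), nImages = 3, cellsPerImage = 15,
                    seed = 4)
  sub <- simulateAnnotator(gt, annotatorProfile(), seed = 1, annotatorId = "p")
  expect_equal(competitionAccuracy(gt, sub)$accuracy, 100)
  m <- perClassMetrics(gt, sub)
  present <- m$TP + m$FN > 0
  expect_true(all(m$F1[present] == 1))
})

test_that("half-correct submission scores 50 and empty classes are NA", {
  gt <- makeSet(x = seq(130, 320, by = 10), y = 150, cls = "PT")  # 20 cells
  keep <- annotations(gt)[1:10, ]
  sub <- AnnotationSet(transform(keep, annotator_id = "a"), imageTable(gt),
                       role = "submission")
  acc <- competitionAccuracy(gt, sub)
  expect_equal(acc$n_correct, 10); expect_equal(acc$n_total, 20)
  expect_equal(acc$accuracy, 50)
  m <- perClassMetrics(gt, sub)
  nnt <- m[m$cell_class == "NNT", ]  # 0 gt, 0 pred: all rates undefined
  expect_true(is.na(nnt$TPR) && is.na(nnt$PPV) && is.na(nnt$F1))
})

test_that("accuracy is refused when there is no ground truth", {
  gt <- AnnotationSet(data.frame(), imageRecords("t1"))
  sub <- makeSet(x = 150, y = 150, cls = "PT", role = "submission")
  expect_error(competitionAccuracy(gt, sub), "undefined")
})

test_that("accuracy equals 100 x pooled class-aware recall", {
  set.seed(6)
  gt <- fixedLayout(superchargerLevel(), nImages = 8, seed = 6)
  prof <- annotatorProfile(detectProb = c(PT = 0.9, NT = 0.7, PNT = 0.6,
                                          NNT = 0.5),
                           jitterSigma = 3, spuriousRate = 2)
  sub <- simulateAnnotator(gt, prof, seed = 7)
  acc <- competitionAccuracy(gt, sub)
  m <- perClassMetrics(gt, sub)
  expect_equal(acc$accuracy, 100 * m$TPR[m$cell_class == "ALL"])
})

test_that("simulated detection probability drives accuracy", {
  gt <- fixedLayout(superchargerLevel(), nImages = 100, seed = 10)  # 2000 cells
  sub <- simulateAnnotator(gt, annotatorProfile(detectProb = 0.7), seed = 11)
  acc <- competitionAccuracy(gt, sub)
  expect_equal(acc$n_total, 2000)
  tol <- 4 * sqrt(0.7 * 0.3 / 2000) * 100  # binomial 4-sigma band
  expect_gt(acc$accuracy, 70 - tol)
  expect_lt(acc$accuracy, 70 + tol)
})

test_that("confusion matrix isolates relabelling and margins add up", {
  set.seed(8)
  gt <- fixedLayout(superchargerLevel(), nImages = 10, seed = 8)
  # relabel every detected PNT as PT, zero jitter, no misses
  conf <- diag(4); conf[3, ] <- c(1, 0, 0, 0)
  sub <- simulateAnnotator(gt, annotatorProfile(confusion = conf), seed = 9)
  cm <- confusionMatrix(gt, sub)
  gtCounts <- table(factor(annotations(gt)$cell_class, levels = cellClasses()))
  expect_equal(unname(rowSums(cm)[cellClasses()]), as.vector(gtCounts))
  expect_equal(cm["PNT", "PT"], unname(gtCounts["PNT"]))
  expect_equal(cm["PNT", "PNT"], 0)
  expect_equal(sum(cm[, "NONE"]), 0)  # nothing missed
  # perfect annotator: purely diagonal
  perfect <- simulateAnnotator(gt, annotatorProfile(), seed = 2)
  cmP <- confusionMatrix(gt, perfect)
  expect_equal(sum(cmP) - sum(diag(cmP)), 0)
  # blind annotator: all gt mass in the NONE column
  blind <- simulateAnnotator(gt, annotatorProfile(detectProb = 0), seed = 3)
  cmB <- confusionMatrix(gt, blind)
  expect_equal(unname(cmB[cellClasses(), "NONE"]), as.vector(gtCounts))
})

test_that("swapping roles transposes the confusion matrix", {
  set.seed(14)
  gt <- fixedLayout(superchargerLevel(), nImages = 5, seed = 14)
  conf <- diag(4); conf[3, ] <- c(0.5, 0, 0.5, 0)
  sub <- simulateAnnotator(gt, annotatorProfile(detectProb = 0.8,
                                                jitterSigma = 2,
                                                confusion = conf,
                                                spuriousRate = 2), seed = 15)
  cm <- confusionMatrix(gt, sub)
  gt2 <- sub; gt2@role <- "ground_truth"
  sub2 <- gt; sub2@role <- "submission"
  cm2 <- confusionMatrix(gt2, sub2)
  expect_equal(unclass(cm), t(cm2), ignore_attr = TRUE)
  # and FP/FN swap while TP and F1 stay put
  m <- perClassMetrics(gt, sub); m2 <- perClassMetrics(gt2, sub2)
  expect_equal(m$TP, m2$TP)
  expect_equal(m$FP, m2$FN)
  expect_equal(m$F1, m2$F1)
})

test_that("aggregation pools raw counts before deriving rates", {
  m1 <- dotmatch:::classMetricsFromCounts("PT", 1, 0, 1)
  m2 <- dotmatch:::classMetricsFromCounts("PT", 3, 2, 1)
  agg <- aggregateMetrics(list(m1, m2))
  expect_equal(agg$TP, 4L); expect_equal(agg$FP, 2L); expect_equal(agg$FN, 2L)
  expect_equal(agg$F1, 2 * (4 / 6) * (4 / 6) / (8 / 6))
  expect_equal(round(agg$F1, 4), 0.6667)
  expect_error(aggregateMetrics(list()), "no metrics")
  # single element: aggregation is the identity on counts and rates
  expect_equal(aggregateMetrics(list(m2)), m2)
})

test_that("F1 sits between min(TPR, PPV) and their geometric mean", {
  set.seed(19)
  for (rep in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    m <- dotmatch:::classMetricsFromCounts("PT", tp, fp, fn)
    if (!is.na(m$F1)) {
      expect_gte(m$F1, min(m$TPR, m$PPV) - 1e-12)
      expect_lte(m$F1, sqrt(m$TPR * m$PPV) + 1e-12)
      expect_equal(m$F1 == 1, tp > 0 && fp == 0 && fn == 0)
    }
  }
})

test_that("F1 distribution summarises a cohort and reports undefined cases", {
  set.seed(23)
  gt <- fixedLayout(superchargerLevel(), nImages = 6, seed = 23)
  cohort <- lapply(1:6, function(i)
    perClassMetrics(gt, simulateAnnotator(
      gt, annotatorProfile(detectProb = 0.8, jitterSigma = 2), seed = 30 + i)))
  names(cohort) <- paste0("kid_", 1:6)
  d <- f1Distribution(cohort)
  pt <- d[d$cell_class == "PT", ]
  expect_equal(pt$n + pt$n_undefined, 6)
  expect_true(pt$min <= pt$q25 && pt$q25 <= pt$median &&
              pt$median <= pt$q75 && pt$q75 <= pt$max)
  expect_gte(pt$mean, pt$min); expect_lte(pt$mean, pt$max)
})

test_that("mean F1 over identical simulated annotators is stable", {
  set.seed(27)
  gt <- fixedLayout(superchargerLevel(), nImages = 10, seed = 27)
  prof <- annotatorProfile(detectProb = 0.8, jitterSigma = 2)
  f1 <- vapply(1:10, function(i) {
    m <- perClassMetrics(gt, simulateAnnotator(gt, prof, seed = 100 + i))
    m$F1[m$cell_class == "ALL"]
  }, numeric(1))
  # detection 0.8, no confusion, no spurious dots: F1 = 2p/(1+p) ~ 0.889
  expect_lt(abs(mean(f1) - 2 * 0.8 / 1.8), 0.02)
})
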