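test_that("layout generation is seeded, separated and respects the region", {
  lvl <- superchargerLevel()
  a <- generateLayout(lvl, nImages = 4, seed = 101)
  b <- generateLayout(lvl, nImages = 4, seed = 101)
  expect_identical(annotations(a), annotations(b))  # full determinism
  expect_false(identical(annotations(a),
                         annotations(generateLayout(lvl, nImages = 4, seed = 102))))

  ann <- annotations(a)
  im <- imageTable(a)
  expect_true(all(ann$x >= 128 & ann$x < 384 & ann$y >= 128 & ann$y < 384))
  # pairwise separation within every image
  for (id in im$image_id) {
    d <- ann[ann$image_id == id, ]
    dm <- as.matrix(dist(d[, c("x", "y")]))
    expect_true(all(dm[upper.tri(dm)] >= 30))
  }
  expect_equal(nDots(generateLayout(lvl, nImages = 0, seed = 1)), 0)
})

test_that("infeasible density errors instead of looping forever", {
  lvl <- superchargerLevel()
  layout <- layoutConfig(cellsPerImage = c(200, 200), minSeparation = 30)
  expect_error(generateLayout(lvl, nImages = 1, layout = layout, seed = 1),
               "infeasible")
})

test_that("layout classes follow the level mix", {
  lvl <- superchargerLevel()
  gt <- fixedLayout(lvl, nImages = 500, seed = 77)  # 10,000 cells
  cls <- annotations(gt)$cell_class
  tumour <- mean(cls %in% c("PT", "NT"))
  tol <- 4 * sqrt(0.81 * 0.19 / length(cls))
  expect_equal(length(cls), 10000)
  expect_gt(tumour, 0.81 - tol)
  expect_lt(tumour, 0.81 + tol)
  # a single-class level only produces that class
  mild <- competitionLevels(defaultCompetition("main"))[["Mild"]]
  expect_true(all(annotations(fixedLayout(mild, 2, seed = 3))$cell_class == "PT"))
})

test_that("a perfect profile reproduces the ground truth exactly", {
  gt <- fixedLayout(superchargerLevel(), nImages = 3, seed = 5)
  sub <- simulateAnnotator(gt, annotatorProfile(), seed = 6, annotatorId = "p")
  a <- annotations(gt); b <- annotations(sub)
  expect_equal(b[c("image_id", "x", "y", "cell_class")],
               a[c("image_id", "x", "y", "cell_class")])
  m <- perClassMetrics(gt, sub)
  expect_true(all(m$F1[m$TP + m$FN > 0] == 1))
})

test_that("simulation is deterministic in the seed", {
  gt <- fixedLayout(superchargerLevel(), nImages = 3, seed = 5)
  prof <- annotatorProfile(detectProb = 0.7, jitterSigma = 3, spuriousRate = 2)
  s1 <- simulateAnnotator(gt, prof, seed = 8)
  s2 <- simulateAnnotator(gt, prof, seed = 8)
  expect_identical(annotations(s1), annotations(s2))
})

test_that("per-class detection probability shows up as recall", {
  mild <- competitionLevels(defaultCompetition("main"))[["Mild"]]
  gt <- fixedLayout(mild, nImages = 100, seed = 12)  # 2,000 PT cells
  sub <- simulateAnnotator(gt, annotatorProfile(detectProb = 0.7), seed = 13)
  m <- perClassMetrics(gt, sub)
  recall <- m$TPR[m$cell_class == "PT"]
  tol <- 4 * sqrt(0.7 * 0.3 / 2000)
  expect_gt(recall, 0.7 - tol); expect_lt(recall, 0.7 + tol)
})

test_that("confusion sends about half of detected PNT cells to PT", {
  lvl <- superchargerLevel()
  gt <- fixedLayout(lvl, nImages = 150, seed = 16)  # ~360 PNT cells
  conf <- diag(4); conf[3, ] <- c(0.5, 0, 0.5, 0)
  sub <- simulateAnnotator(gt, annotatorProfile(confusion = conf), seed = 17)
  cm <- confusionMatrix(gt, sub)
  nPNT <- sum(annotations(gt)$cell_class == "PNT")
  frac <- cm["PNT", "PT"] / nPNT
  tol <- 4 * sqrt(0.25 / nPNT)
  expect_gt(frac, 0.5 - tol); expect_lt(frac, 0.5 + tol)
})

test_that("profile recovery inverts the generative model", {
  lvl <- superchargerLevel()
  gt <- fixedLayout(lvl, nImages = 60, seed = 20)  # 1,200 cells
  true <- annotatorProfile(detectProb = 0.8, jitterSigma = 2, spuriousRate = 3)
  sub <- simulateAnnotator(gt, true, seed = 21)
  est <- recoverProfile(gt, sub)
  expect_s4_class(est, "AnnotatorProfileEstimate")
  expect_true(est@sigmaReliable)
  expect_lt(max(abs(detectProb(est) - 0.8) / 0.8), 0.1)
  expect_lt(abs(jitterSigma(est) - 2) / 2, 0.1)
  expect_lt(abs(spuriousRate(est) - 3) / 3, 0.15)
  expect_lt(max(abs(diag(confusionRows(est)) - 1)), 0.05)
})

test_that("a perfect annotator recovers as one", {
  gt <- fixedLayout(superchargerLevel(), nImages = 5, seed = 22)
  est <- recoverProfile(gt, simulateAnnotator(gt, annotatorProfile(), seed = 23))
  expect_equal(unname(detectProb(est)), rep(1, 4))
  expect_equal(jitterSigma(est), 0)
  expect_equal(unclass(confusionRows(est)), diag(4), ignore_attr = TRUE)
  expect_equal(spuriousRate(est), 0)
})

test_that("few matched pairs flag the sigma estimate as unreliable", {
  gt <- makeSet(x = c(150, 200, 250), y = 150, cls = "PT")
  sub <- makeSet(x = c(151, 201, 251), y = 150, cls = "PT",
                 annotator = "a", role = "submission")
  est <- recoverProfile(gt, sub)
  expect_false(est@sigmaReliable)
  expect_equal(est@nPairs, 3L)
})

test_that("jitter near the radius biases the sigma estimate low", {
  # sigma = 10 against radius 14: paired distances are truncated at 14,
  # so the Rayleigh-mean estimator must come out below the true sigma
  lvl <- superchargerLevel()
  gt <- fixedLayout(lvl, nImages = 100, seed = 24)
  sub <- simulateAnnotator(gt, annotatorProfile(jitterSigma = 10), seed = 25)
  est <- recoverProfile(gt, sub)
  expect_true(est@sigmaReliable)
  expect_lt(jitterSigma(est), 10)
})

test_that("F1 never improves when jitter grows", {
  lvl <- superchargerLevel()
  gt <- fixedLayout(lvl, nImages = 4, seed = 26)
  meanF1 <- function(sigma) {
    mean(vapply(1:20, function(i) {
      sub <- simulateAnnotator(gt, annotatorProfile(jitterSigma = sigma),
                               seed = 3000 + 100 * sigma + i)
      m <- perClassMetrics(gt, sub)
      m$F1[m$cell_class == "ALL"]
    }, numeric(1)))
  }
  f1 <- vapply(c(0, 4, 8, 12, 16), meanF1, numeric(1))
  expect_true(all(diff(f1) <= 1e-9))
})
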