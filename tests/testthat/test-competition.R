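test_that("packaged editions match the competition setup", {
  main <- defaultCompetition("main")
  lv <- competitionLevels(main)
  expect_equal(names(lv), c("Mild", "Hot", "Spicy", "Supercharger"))
  expect_equal(vapply(lv, function(l) l@nImages, integer(1)),
               c(Mild = 20L, Hot = 40L, Spicy = 60L, Supercharger = 80L))
  expect_equal(vapply(lv, function(l) length(l@classes), integer(1)),
               c(Mild = 1L, Hot = 2L, Spicy = 3L, Supercharger = 4L))
  # one class added per level, introduced in the order PT, NT, PNT, NNT
  for (i in seq_along(lv))
    expect_equal(lv[[i]]@classes, cellClasses()[seq_len(i)])
  pr <- practiceLevels(main)
  expect_equal(vapply(pr, function(l) l@nImages, integer(1)),
               c(Mild = 5L, Hot = 5L))
  expect_equal(pr[["Mild"]]@classes, "PT")
  expect_equal(pr[["Hot"]]@classes, c("PT", "NT"))

  pilot <- defaultCompetition("pilot")
  plv <- competitionLevels(pilot)
  expect_equal(vapply(plv, function(l) l@nImages, integer(1)),
               c(Mild = 20L, Hot = 30L, Spicy = 50L))
  for (l in plv) expect_equal(l@classes, cellClasses())  # all 4 at every level

  expect_error(defaultCompetition("grande"), "arg")
})

test_that("Supercharger mix makes 81% of cells tumour cells", {
  lvl <- superchargerLevel()
  expect_equal(unname(lvl@classMix["PT"]), 0.21)
  expect_equal(unname(lvl@classMix["NT"]), 0.60)
  expect_equal(sum(lvl@classMix), 1)
})

test_that("the pass bound is inclusive at exactly 50", {
  lvl <- levelConfig("Mild", 20, "PT", c(PT = 1))
  expect_true(gateLevel(50.0, lvl))    # "at least 50%"
  expect_false(gateLevel(49.99, lvl))
  expect_true(gateLevel(100, lvl))
  expect_true(gateLevel(list(accuracy = 62, n_correct = 31, n_total = 50), lvl))
})

test_that("gating is monotone in the number of correct cells", {
  lvl <- levelConfig("Hot", 40, c("PT", "NT"), c(PT = 0.4, NT = 0.6))
  nTotal <- 200
  passes <- vapply(0:nTotal, function(k) gateLevel(100 * k / nTotal, lvl),
                   logical(1))
  expect_true(all(diff(passes) >= 0))  # once passing, more correct still passes
})

test_that("leaderboards rank by accuracy with documented tie-breaks", {
  scores <- data.frame(annotator_id = c("carol", "alice", "bob"),
                       level = "Mild", accuracy = c(87, 99, 90))
  lvl <- competitionLevels(defaultCompetition("main"))[["Mild"]]
  b <- rankLeaderboard(scores, lvl)
  expect_equal(b$accuracy, c(99, 90, 87))
  expect_equal(b$rank, 1:3)
  expect_true(all(b$passed))

  # equal scores, no timestamps: lexicographic by annotator_id
  tie <- data.frame(annotator_id = c("zoe", "amy"), level = "Mild",
                    accuracy = c(80, 80))
  expect_equal(rankLeaderboard(tie, lvl)$annotator_id, c("amy", "zoe"))

  # with timestamps the earlier submission wins the tie
  tie$timestamp <- c(1, 2)
  expect_equal(rankLeaderboard(tie, lvl)$annotator_id, c("zoe", "amy"))

  # repeated attempts: the best score per annotator is kept
  rep <- data.frame(annotator_id = "amy", level = "Mild",
                    accuracy = c(40, 72, 55))
  expect_equal(rankLeaderboard(rep, lvl)$accuracy, 72)

  expect_equal(nrow(rankLeaderboard(scores[0, ], lvl)), 0)
})

test_that("funnel percentages reproduce printed-report arithmetic", {
  # 95 of 98 registrants participated: 97%; 52 of 61 passed: 85%
  expect_equal(dotmatch:::roundHalfUp(100 * 95 / 98), 97)
  expect_equal(dotmatch:::roundHalfUp(100 * 52 / 61), 85)
  expect_equal(dotmatch:::roundHalfUp(100 * 91 / 95), 96)
  # 22 of 28 is 79% from the counts (not the sometimes-quoted 81)
  expect_equal(dotmatch:::roundHalfUp(100 * 22 / 28), 79)

  cfg <- defaultCompetition("main")
  mkScores <- function(level, nEnter, nPass) {
    data.frame(annotator_id = sprintf("%s_%03d", level, seq_len(nEnter)),
               level = level,
               accuracy = c(rep(80, nPass), rep(10, nEnter - nPass)))
  }
  scores <- rbind(mkScores("Mild", 95, 91), mkScores("Hot", 61, 52),
                  mkScores("Spicy", 28, 22), mkScores("Supercharger", 22, 15))
  fs <- funnelStats(scores, cfg, nRegistered = 98)
  expect_equal(fs$participation_pct, 97)
  expect_equal(fs$levels$pass_pct[fs$levels$level == "Mild"], 96)
  expect_equal(fs$levels$pass_pct[fs$levels$level == "Hot"], 85)
  expect_equal(fs$levels$pass_pct[fs$levels$level == "Spicy"], 79)
  expect_true(all(fs$levels$n_passed <= fs$levels$n_entered))
  expect_true(all(fs$levels$pass_pct >= 0 & fs$levels$pass_pct <= 100))
  # 0 of 10 passing is an honest 0%
  fs0 <- funnelStats(mkScores("Mild", 10, 0), cfg)
  expect_equal(fs0$levels$pass_pct[1], 0)
  # a level nobody entered is undefined, not zero
  expect_true(is.na(fs0$levels$pass_pct[2]))
})

test_that("a cohort whose skill degrades with difficulty yields a shrinking funnel", {
  set.seed(55)
  cfg <- defaultCompetition("main")
  lv <- competitionLevels(cfg)
  detect <- c(Mild = 0.9, Hot = 0.75, Spicy = 0.6, Supercharger = 0.45)
  nKids <- 12
  rows <- list()
  entered <- paste0("kid_", seq_len(nKids))
  for (lname in names(lv)) {
    if (!length(entered)) break
    gt <- fixedLayout(lv[[lname]], nImages = 3, cellsPerImage = 15,
                      seed = match(lname, names(lv)))
    accs <- vapply(seq_along(entered), function(i) {
      sub <- simulateAnnotator(gt, annotatorProfile(detectProb = unname(detect[lname]),
                                                    jitterSigma = 2),
                               seed = 1000 * match(lname, names(lv)) + i,
                               annotatorId = entered[i])
      competitionAccuracy(gt, sub)$accuracy
    }, numeric(1))
    rows[[lname]] <- data.frame(annotator_id = entered, level = lname,
                                accuracy = accs)
    entered <- entered[accs >= lv[[lname]]@passThreshold]  # gate to next level
  }
  fs <- funnelStats(do.call(rbind, rows), cfg)
  ent <- fs$levels$n_entered
  expect_true(all(diff(ent[!is.na(ent)]) <= 0))
  expect_true(all(fs$levels$n_passed <= fs$levels$n_entered))
})

test_that("the 14 px radius converts to 3.5 um at scan resolution", {
  expect_equal(radiusMicrons(14, 0.25), 3.5)
  expect_error(radiusMicrons(0), "radius")
})
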