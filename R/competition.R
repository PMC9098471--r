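#' Packaged competition configurations
#'
#' Loads the configuration of one of the two competition editions from the
#' versioned JSON files shipped with the package. The main edition has four
#' competition levels (Mild, Hot, Spicy, Supercharger) with 20, 40, 60 and
#' 80 images and 1, 2, 3 and 4 cell classes respectively, classes being
#' introduced in the order PT, NT, PNT, NNT, plus two practice levels of 5
#' images each ({PT}, then {PT, NT}). The pilot edition has three levels
#' (20, 30, 50 images) with all four classes at every level. Every level
#' gates at 50% accuracy, inclusively.
#'
#' Class mixes follow the reported Supercharger composition (21% PT, 60% NT,
#' the remaining 19% non-tumour, so 81% tumour cells overall); the split of
#' the non-tumour remainder and the lower-level mixes are package defaults.
#'
#' @param edition `"main"` or `"pilot"`; alternatively `path` may point to a
#'   custom JSON file of the same schema.
#' @param path optional explicit path to a configuration JSON.
#' @return A `CompetitionConfig`.
#' @examples
#' defaultCompetition("main")
#' @export
defaultCompetition <- function(edition = c("main", "pilot"), path = NULL) {
  if (is.null(path)) {
    edition <- match.arg(edition)
    path <- system.file("extdata", "config",
                        paste0("competition_", edition, ".json"),
                        package = "dotmatch", mustWork = TRUE)
  }
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  parseLevel <- function(l) {
    levelConfig(l$name, l$n_images, unlist(l$classes),
                unlist(l$class_mix), l$pass_threshold)
  }
  new("CompetitionConfig", edition = obj$edition,
      levels = lapply(obj$levels, parseLevel),
      practiceLevels = lapply(obj$practice_levels, parseLevel))
}

#' Level gating
#'
#' A participant unlocks the next level when at least the threshold
#' percentage of the current level's cells is correctly annotated; the bound
#' is inclusive, so exactly 50.0 passes at the default threshold.
#'
#' @param score a [competitionAccuracy()] result (or a number on the 0-100
#'   scale).
#' @param level the [levelConfig()] being gated.
#' @return `TRUE` iff the accuracy meets the threshold.
#' @examples
#' lvl <- levelConfig("Mild", 20, "PT", c(PT = 1))
#' gateLevel(50, lvl)     # TRUE  ("at least 50%")
#' gateLevel(49.99, lvl)  # FALSE
#' @export
gateLevel <- function(score, level) {
  stopifnot(is(level, "LevelConfig"))
  acc <- if (is.list(score)) score$accuracy else score
  stopifnot(is.numeric(acc), length(acc) == 1)
  acc >= level@passThreshold
}

# Best score per annotator per level ("participants could enter each level
# as many times as they could"): keep the maximum accuracy; ties keep the
# earliest timestamp when present.
.bestScores <- function(scores) {
  ord <- order(scores$annotator_id, scores$level, -scores$accuracy,
               if (!is.null(scores$timestamp)) scores$timestamp else
                 seq_len(nrow(scores)))
  s <- scores[ord, , drop = FALSE]
  s[!duplicated(s[c("annotator_id", "level")]), , drop = FALSE]
}

#' Rank a leaderboard for one level
#'
#' Orders annotators by descending accuracy at a level, keeping each
#' annotator's best score. Ties break by earlier submission timestamp when a
#' `timestamp` column is present, otherwise stably by `annotator_id`
#' (lexicographic). An optional category filter supports separate primary /
#' secondary / sixth-form rankings.
#'
#' @param scores data.frame with columns `annotator_id`, `level`,
#'   `accuracy` and optionally `category` and `timestamp`.
#' @param level a [levelConfig()] or level name.
#' @param category optional category to rank within.
#' @return data.frame of the ranked entries with a `rank` column and a
#'   `passed` flag from [gateLevel()] when `level` is a `LevelConfig`.
#' @export
rankLeaderboard <- function(scores, level, category = NULL) {
  lvlName <- if (is(level, "LevelConfig")) levelName(level) else as.character(level)
  s <- scores[scores$level == lvlName, , drop = FALSE]
  if (!is.null(category) && !is.null(s$category))
    s <- s[s$category == category, , drop = FALSE]
  if (!nrow(s)) {
    s$rank <- integer()
    return(s)
  }
  s <- .bestScores(s)
  ord <- order(-s$accuracy,
               if (!is.null(s$timestamp)) s$timestamp else rep(0, nrow(s)),
               s$annotator_id)
  s <- s[ord, , drop = FALSE]
  s$rank <- seq_len(nrow(s))
  if (is(level, "LevelConfig"))
    s$passed <- vapply(s$accuracy, gateLevel, logical(1), level = level)
  rownames(s) <- NULL
  s
}

#' Participation-funnel statistics
#'
#' Per level: how many annotators entered (have a score), how many passed
#' the gate, and the pass percentage rounded half-up to the nearest integer
#' for parity with printed competition reports. With `nRegistered` given,
#' the overall registration-to-participation percentage (entrants of the
#' first level over registrants) is included. Levels with zero entrants get
#' an `NA` percentage (undefined), never a silent zero.
#'
#' @param scores data.frame as in [rankLeaderboard()]; best score per
#'   annotator per level is used.
#' @param config a [defaultCompetition()] configuration.
#' @param nRegistered optional number of registrants.
#' @return list with `levels` (data.frame: `level`, `n_entered`, `n_passed`,
#'   `pass_pct`) and, when `nRegistered` is given, `n_registered`,
#'   `n_participated` and `participation_pct`.
#' @examples
#' cfg <- defaultCompetition("main")
#' scores <- data.frame(annotator_id = sprintf("kid_%02d", 1:61),
#'                      level = "Hot",
#'                      accuracy = c(rep(75, 52), rep(20, 9)))
#' funnelStats(scores, cfg)$levels  # 52 of 61 pass the Hot level: 85%
#' @export
funnelStats <- function(scores, config, nRegistered = NULL) {
  stopifnot(is(config, "CompetitionConfig"))
  best <- if (nrow(scores)) .bestScores(scores) else scores
  rows <- lapply(config@levels, function(lvl) {
    s <- best[best$level == levelName(lvl), , drop = FALSE]
    nEntered <- nrow(s)
    nPassed <- sum(vapply(s$accuracy, gateLevel, logical(1), level = lvl))
    data.frame(level = levelName(lvl), n_entered = nEntered, n_passed = nPassed,
               pass_pct = if (nEntered > 0)
                 roundHalfUp(100 * nPassed / nEntered) else NA_real_)
  })
  out <- list(levels = do.call(rbind, rows))
  if (!is.null(nRegistered)) {
    firstLevel <- levelName(config@levels[[1]])
    nPart <- length(unique(best$annotator_id[best$level == firstLevel]))
    out$n_registered <- nRegistered
    out$n_participated <- nPart
    out$participation_pct <- if (nRegistered > 0)
      roundHalfUp(100 * nPart / nRegistered) else NA_real_
  }
  out
}
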