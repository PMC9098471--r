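#' One-to-one dot matching within a distance radius
#'
#' Pairs predicted dots with ground-truth dots of one image so that a pair
#' is only allowed when the Euclidean distance is at most the matching
#' radius (14 px, i.e. 3.5 um at 0.25 um/px, by default). Among all
#' one-to-one assignments the solver maximises the number of pairs first and
#' breaks ties by minimum total paired distance; this is the standard
#' detection-evaluation formalisation (a min-cost maximum-cardinality
#' bipartite assignment on radius-feasible edges) and is deterministic for a
#' fixed input. With `classAware = TRUE` matching is computed independently
#' within each cell class, so a dot of the wrong class can never count as
#' correct.
#'
#' The solver decomposes the radius-feasibility graph into connected
#' components and runs successive shortest augmenting paths within each;
#' an exhaustive oracle, [bruteForceMatch()], verifies it on small
#' instances.
#'
#' @param gt,pred data.frames of dots of one image with columns `x`, `y`
#'   and `cell_class`.
#' @param config a [matchConfig()].
#' @return A `MatchResult`: `matchedPairs()` gives one row per pair
#'   (`gt`/`pred` row indices and their distance); `unmatchedGT()` and
#'   `unmatchedPred()` the residual row indices (misses and spurious dots).
#' @examples
#' gt <- data.frame(x = c(0, 10), y = 0, cell_class = "PT")
#' pred <- data.frame(x = c(9, 19), y = 0, cell_class = "PT")
#' matchPoints(gt, pred, matchConfig())  # both pairs, not the greedy one
#' @export
matchPoints <- function(gt, pred, config = matchConfig()) {
  stopifnot(is(config, "MatchConfig"))
  validObject(config)
  gt <- as.data.frame(gt); pred <- as.data.frame(pred)
  n <- nrow(gt); m <- nrow(pred)
  if (config@classAware && (n || m)) {
    pairs <- list(); ugt <- list(); upred <- list()
    for (cl in unique(c(gt$cell_class, pred$cell_class))) {
      gi <- which(gt$cell_class == cl); pi <- which(pred$cell_class == cl)
      sub <- .matchXY(gt$x[gi], gt$y[gi], pred$x[pi], pred$y[pi], config@radius)
      pairs[[cl]] <- data.frame(gt = gi[sub$pairs[, 1]],
                                pred = pi[sub$pairs[, 2]],
                                distance = sub$pairs[, 3])
      ugt[[cl]] <- gi[sub$unmatchedGT]; upred[[cl]] <- pi[sub$unmatchedPred]
    }
    pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
    if (is.null(pairs))
      pairs <- data.frame(gt = integer(), pred = integer(), distance = numeric())
    res <- list(pairs = pairs,
                unmatchedGT = sort(unlist(ugt, use.names = FALSE)),
                unmatchedPred = sort(unlist(upred, use.names = FALSE)))
  } else {
    sub <- .matchXY(gt$x, gt$y, pred$x, pred$y, config@radius)
    res <- list(pairs = data.frame(gt = sub$pairs[, 1], pred = sub$pairs[, 2],
                                   distance = sub$pairs[, 3]),
                unmatchedGT = sub$unmatchedGT, unmatchedPred = sub$unmatchedPred)
  }
  ord <- order(res$pairs$gt)
  new("MatchResult", pairs = res$pairs[ord, , drop = FALSE],
      unmatchedGT = as.integer(res$unmatchedGT),
      unmatchedPred = as.integer(res$unmatchedPred),
      nGT = n, nPred = m, radius = config@radius)
}

# Min-cost max-cardinality matching on radius-feasible edges.
# Returns pairs as a 3-column matrix (gt index, pred index, distance) plus
# unmatched index vectors, all in local (1-based) indices.
.matchXY <- function(gx, gy, px, py, radius) {
  n <- length(gx); m <- length(px)
  empty <- list(pairs = matrix(numeric(), 0, 3),
                unmatchedGT = seq_len(n), unmatchedPred = seq_len(m))
  if (n == 0 || m == 0) return(empty)
  D <- sqrt(outer(gx, px, "-")^2 + outer(gy, py, "-")^2)
  feas <- D <= radius
  if (!any(feas)) return(empty)
  # Connected components of the feasibility graph: dots in different
  # components can never compete for the same partner, so each component is
  # solved independently (they are small when cells are well separated).
  compG <- rep(0L, n); compP <- rep(0L, m); nc <- 0L
  for (s in seq_len(n)) {
    if (compG[s] || !any(feas[s, ])) next
    nc <- nc + 1L
    queueG <- s
    while (length(queueG)) {
      compG[queueG] <- nc
      js <- which(colSums(feas[queueG, , drop = FALSE]) > 0 & compP == 0L)
      if (!length(js)) break
      compP[js] <- nc
      queueG <- which(rowSums(feas[, js, drop = FALSE]) > 0 & compG == 0L)
    }
  }
  matchL <- rep(0L, n); matchR <- rep(0L, m)
  for (cc in seq_len(nc)) {
    gi <- which(compG == cc); pi <- which(compP == cc)
    sub <- .sspMatch(D[gi, pi, drop = FALSE], feas[gi, pi, drop = FALSE])
    matchL[gi[sub$left > 0]] <- pi[sub$left[sub$left > 0]]
  }
  paired <- which(matchL > 0L)
  pairs <- cbind(paired, matchL[paired], D[cbind(paired, matchL[paired])])
  list(pairs = pairs,
       unmatchedGT = which(matchL == 0L),
       unmatchedPred = setdiff(seq_len(m), matchL[paired]))
}

# Successive shortest augmenting paths (Bellman-Ford on the residual graph).
# Augmenting whenever a path exists, always along the cheapest one, yields
# the minimum-total-distance matching among those of maximum cardinality.
.sspMatch <- function(D, feas) {
  n <- nrow(D); m <- ncol(D)
  matchL <- rep(0L, n); matchR <- rep(0L, m)
  eps <- 1e-9
  repeat {
    distL <- ifelse(matchL == 0L, 0, Inf)
    distR <- rep(Inf, m)
    prevR <- rep(0L, m)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        if (!is.finite(distL[i])) next
        for (j in seq_len(m)) {
          if (!feas[i, j] || matchL[i] == j) next
          nd <- distL[i] + D[i, j]
          if (nd < distR[j] - eps) {
            distR[j] <- nd; prevR[j] <- i; changed <- TRUE
          }
        }
      }
      for (j in seq_len(m)) {
        i <- matchR[j]
        if (i > 0L && is.finite(distR[j])) {
          nd <- distR[j] - D[i, j]
          if (nd < distL[i] - eps) { distL[i] <- nd; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    free <- which(matchR == 0L & is.finite(distR))
    if (!length(free)) break
    jstar <- free[which.min(distR[free])]
    # Walk back: each intermediate left node was reached via its matched edge.
    j <- jstar
    repeat {
      i <- prevR[j]
      pj <- matchL[i]
      matchL[i] <- j; matchR[j] <- i
      if (pj == 0L) break
      j <- pj
    }
  }
  list(left = matchL, right = matchR)
}

#' Exhaustive matching oracle
#'
#' Enumerates every one-to-one assignment of ground-truth to predicted dots
#' (each dot may also stay unmatched) and returns one achieving the same
#' optimum criterion as [matchPoints()]: maximum number of radius-feasible
#' pairs, ties broken by minimum total distance. Exponential; refuses more
#' than 8 dots on either side. Intended as an independent test oracle for
#' the assignment solver, not for production scoring.
#'
#' @inheritParams matchPoints
#' @return A `MatchResult`.
#' @export
bruteForceMatch <- function(gt, pred, config = matchConfig()) {
  stopifnot(is(config, "MatchConfig"))
  validObject(config)
  gt <- as.data.frame(gt); pred <- as.data.frame(pred)
  if (nrow(gt) > 8 || nrow(pred) > 8)
    stop("bruteForceMatch is exponential; at most 8 dots per side",
         call. = FALSE)
  n <- nrow(gt); m <- nrow(pred)
  if (config@classAware && (n || m)) {
    # reuse matchPoints' per-class decomposition with this solver
    cfg0 <- matchConfig(config@radius, config@resolution, classAware = FALSE)
    pairs <- list(); ugt <- list(); upred <- list()
    for (cl in unique(c(gt$cell_class, pred$cell_class))) {
      gi <- which(gt$cell_class == cl); pi <- which(pred$cell_class == cl)
      sub <- bruteForceMatch(gt[gi, , drop = FALSE], pred[pi, , drop = FALSE], cfg0)
      p <- matchedPairs(sub)
      pairs[[cl]] <- data.frame(gt = gi[p$gt], pred = pi[p$pred],
                                distance = p$distance)
      ugt[[cl]] <- gi[unmatchedGT(sub)]; upred[[cl]] <- pi[unmatchedPred(sub)]
    }
    pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
    ord <- order(pairs$gt)
    return(new("MatchResult", pairs = pairs[ord, , drop = FALSE],
               unmatchedGT = sort(as.integer(unlist(ugt, use.names = FALSE))),
               unmatchedPred = sort(as.integer(unlist(upred, use.names = FALSE))),
               nGT = n, nPred = m, radius = config@radius))
  }
  D <- if (n && m) sqrt(outer(gt$x, pred$x, "-")^2 + outer(gt$y, pred$y, "-")^2)
       else matrix(numeric(), n, m)
  best <- new.env()
  best$count <- -1L; best$cost <- Inf; best$assign <- rep(0L, n)
  recurse <- function(i, used, assign, count, cost) {
    if (i > n) {
      if (count > best$count ||
          (count == best$count && cost < best$cost - 1e-12)) {
        best$count <- count; best$cost <- cost; best$assign <- assign
      }
      return(invisible())
    }
    if (count + (n - i + 1L) < best$count) return(invisible())  # bound
    recurse(i + 1L, used, assign, count, cost)          # leave i unmatched
    for (j in seq_len(m)) {
      if (used[j] || D[i, j] > config@radius) next
      used[j] <- TRUE; assign[i] <- j
      recurse(i + 1L, used, assign, count + 1L, cost + D[i, j])
      used[j] <- FALSE; assign[i] <- 0L
    }
  }
  recurse(1L, rep(FALSE, m), rep(0L, n), 0L, 0)
  paired <- which(best$assign > 0L)
  pairs <- data.frame(gt = paired, pred = best$assign[paired],
                      distance = if (length(paired))
                        D[cbind(paired, best$assign[paired])] else numeric())
  new("MatchResult", pairs = pairs,
      unmatchedGT = setdiff(seq_len(n), paired),
      unmatchedPred = setdiff(seq_len(m), best$assign[paired]),
      nGT = n, nPred = m, radius = config@radius)
}
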