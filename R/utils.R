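#' @importFrom stats rnorm rpois runif quantile setNames aggregate predict sd na.pass
#' @importFrom utils read.csv packageVersion
NULL

# Round half away from zero (base round() is banker's rounding).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of child seeds from one root seed, below 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Convert the matching radius to micrometres
#'
#' Dot matching uses a Euclidean radius in pixels; at a scan resolution given
#' in micrometres per pixel this corresponds to a physical distance. The
#' default 14 px at 0.25 um/px (40X magnification) is 3.5 um.
#'
#' @param radius matching radius in pixels.
#' @param resolution scan resolution in micrometres per pixel.
#' @return The radius in micrometres.
#' @examples
#' radiusMicrons(14, 0.25)  # 3.5
#' @export
radiusMicrons <- function(radius = 14, resolution = 0.25) {
  stopifnot(radius > 0, resolution > 0)
  radius * resolution
}
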