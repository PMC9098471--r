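#' Renderer configuration
#'
#' The renderer draws stylised immunohistochemistry tiles: Ki67-positive
#' nuclei as brown (DAB-like) blobs, negative nuclei as blue
#' (haematoxylin-like) blobs on a pale eosin-tinted background with mild
#' texture noise. Tumour nuclei are drawn from a larger, more variable
#' radius range than non-tumour nuclei. It is a blob renderer for
#' exercising the pipeline and the patch classifier, not a histology
#' simulator.
#'
#' @param tumourRadius,nontumourRadius nucleus radius ranges `c(min, max)`
#'   in pixels.
#' @param positiveColour,negativeColour RGB triplets in `[0, 1]` for
#'   positive (brown) and negative (blue) nuclei.
#' @param backgroundColour background RGB.
#' @param noiseSD standard deviation of the additive texture noise.
#' @return A list of class `RenderConfig`.
#' @export
renderConfig <- function(tumourRadius = c(7, 11), nontumourRadius = c(4, 7),
                         positiveColour = c(0.45, 0.27, 0.10),
                         negativeColour = c(0.25, 0.30, 0.58),
                         backgroundColour = c(0.93, 0.88, 0.90),
                         noiseSD = 0.02) {
  structure(list(tumourRadius = tumourRadius, nontumourRadius = nontumourRadius,
                 positiveColour = positiveColour, negativeColour = negativeColour,
                 backgroundColour = backgroundColour, noiseSD = noiseSD),
            class = "RenderConfig")
}

#' Render one synthetic tile
#'
#' Draws every ground-truth dot of one image as a nucleus blob centred
#' exactly on the annotation coordinate. Deterministic for a fixed seed:
#' the same call produces a byte-identical raster (and PNG, if written).
#'
#' @param gt ground-truth [AnnotationSet()].
#' @param imageId which image of `gt` to render.
#' @param config a [renderConfig()].
#' @param seed integer seed for radii, eccentricity and noise.
#' @param path optional path; when given, the raster is written there as PNG.
#' @return Invisibly, a list with `raster` (height x width x 3 array in
#'   `[0, 1]`) and `annotations` (the sidecar dot table for the image).
#' @export
renderImage <- function(gt, imageId, config = renderConfig(), seed = 1,
                        path = NULL) {
  stopifnot(is(gt, "AnnotationSet"))
  im <- imageTable(gt)
  k <- match(imageId, im$image_id)
  if (is.na(k)) stop("unknown image: ", imageId, call. = FALSE)
  a <- annotations(gt)
  a <- a[a$image_id == imageId, , drop = FALSE]
  w <- as.integer(im$width[k]); h <- as.integer(im$height[k])
  withSeed(seed, {
    img <- array(0, c(h, w, 3))
    for (c3 in 1:3)
      img[, , c3] <- config$backgroundColour[c3] +
        matrix(rnorm(h * w, 0, config$noiseSD), h, w)
    # pixel (row r, col c) has centre (c - 0.5, r - 0.5) in dot coordinates
    for (i in seq_len(nrow(a))) {
      cl <- a$cell_class[i]
      tumour <- cl %in% c("PT", "NT")
      positive <- cl %in% c("PT", "PNT")
      rr <- if (tumour) config$tumourRadius else config$nontumourRadius
      rx <- runif(1, rr[1], rr[2])
      ry <- rx * runif(1, if (tumour) 0.7 else 0.85, 1)  # pleomorphism
      th <- runif(1, 0, pi)
      col <- if (positive) config$positiveColour else config$negativeColour
      x0 <- a$x[i]; y0 <- a$y[i]
      cmin <- max(1L, floor(x0 - rx)); cmax <- min(w, ceiling(x0 + rx) + 1L)
      rmin <- max(1L, floor(y0 - rx)); rmax <- min(h, ceiling(y0 + rx) + 1L)
      cs <- cmin:cmax; rs <- rmin:rmax
      dx <- outer(rep(1, length(rs)), cs - 0.5 - x0)
      dy <- outer(rs - 0.5 - y0, rep(1, length(cs)))
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      q <- (u / rx)^2 + (v / ry)^2
      alpha <- pmax(0, pmin(1, (1.1 - q) / 0.35))  # soft edge
      shade <- 1 - 0.25 * q  # darker core, hint of chromatin texture
      for (c3 in 1:3) {
        patch <- img[rs, cs, c3]
        img[rs, cs, c3] <- patch * (1 - alpha) + alpha * col[c3] * shade
      }
    }
    img <- pmin(pmax(img, 0), 1)
    if (!is.null(path)) png::writePNG(img, path)
    invisible(list(raster = img, annotations = a))
  })
}
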