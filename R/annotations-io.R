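#' Read point annotations from CSV or JSON
#'
#' Reads a dot-annotation table: one row per clicked cell with columns
#' `image_id`, `x`, `y`, `cell_class` and (optionally for ground truth)
#' `annotator_id`. Class labels are matched case-insensitively and stored in
#' canonical upper case. Two dialects are accepted: comma-separated UTF-8
#' with a header, or a JSON mirror with top-level keys `"images"` and
#' `"annotations"` (in which case the embedded image table is used and the
#' `images` argument may be omitted).
#'
#' @param path file to read; dialect chosen by extension (`.json` vs CSV).
#' @param images image-record table from [imageRecords()]; required for CSV
#'   input.
#' @param role `"ground_truth"` or `"submission"`.
#' @return A validated [AnnotationSet()]. Rows referencing unknown images or
#'   unknown class labels raise a validation error naming the offending rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("image_id,x,y,cell_class,annotator_id",
#'              "t1,200,150,pt,GT"), f)
#' readAnnotations(f, imageRecords("t1"), role = "ground_truth")
#' @export
readAnnotations <- function(path, images = NULL,
                            role = c("ground_truth", "submission")) {
  role <- match.arg(role)
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$annotations))
      stop("JSON annotation file must have an 'annotations' key: ", path,
           call. = FALSE)
    ann <- as.data.frame(obj$annotations)
    if (!is.null(obj$images)) images <- as.data.frame(obj$images)
  } else {
    ann <- read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.null(images))
    stop("an image table is required (none embedded in ", path, ")",
         call. = FALSE)
  required <- c("image_id", "x", "y", "cell_class")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknownImg <- !ann$image_id %in% images$image_id
  if (any(unknownImg))
    stop("annotation rows reference unknown images: rows ",
         paste(utils::head(which(unknownImg), 20), collapse = ", "),
         call. = FALSE)
  AnnotationSet(ann, images, role = role)
}

#' Write point annotations to CSV or JSON
#'
#' Coordinates are serialised with full double precision so that
#' `readAnnotations(writeAnnotations(S))` reproduces `S` exactly, duplicates
#' included. Output is byte-stable for a fixed input (LF line endings,
#' fixed column order).
#'
#' @param set an [AnnotationSet()].
#' @param path output path; a `.json` extension selects the JSON dialect
#'   (which embeds the image table), anything else CSV.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(set, path) {
  stopifnot(is(set, "AnnotationSet"))
  validObject(set)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write annotations: directory does not exist: ", dir,
         call. = FALSE)
  a <- annotations(set)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(images = imageTable(set), annotations = a, role = annotationRole(set)),
      path, dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE,
      na = "null")
  } else {
    header <- paste(.validAnnotationCols, collapse = ",")
    lines <- if (nrow(a)) {
      paste(a$image_id, sprintf("%.17g", a$x), sprintf("%.17g", a$y),
            a$cell_class, a$annotator_id, sep = ",")
    } else character()
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Restrict an annotation set to the evaluation regions
#'
#' Keeps exactly the dots falling inside their image's half-open evaluation
#' region (`xmin <= x < xmax`, `ymin <= y < ymax`); by convention the central
#' square of each tile. Dots outside the region are discarded at scoring
#' time and their count reported via the `"discarded"` attribute.
#'
#' The operation is idempotent and never mutates its input.
#'
#' @param set an [AnnotationSet()].
#' @param verbose if `TRUE`, message the number of dots discarded.
#' @return A filtered `AnnotationSet` with attribute `discarded` giving the
#'   number of dots removed.
#' @examples
#' im <- imageRecords("t")
#' s <- AnnotationSet(data.frame(image_id = "t", x = c(128, 384), y = c(128, 200),
#'                               cell_class = c("PT", "NT")), im)
#' nDots(filterToRegion(s))  # 1: x = 384 is outside the half-open bound
#' @export
filterToRegion <- function(set, verbose = FALSE) {
  stopifnot(is(set, "AnnotationSet"))
  a <- annotations(set)
  im <- imageTable(set)
  idx <- match(a$image_id, im$image_id)
  keep <- a$x >= im$region_xmin[idx] & a$x < im$region_xmax[idx] &
          a$y >= im$region_ymin[idx] & a$y < im$region_ymax[idx]
  out <- set
  out@annotations <- a[keep, , drop = FALSE]
  rownames(out@annotations) <- NULL
  attr(out, "discarded") <- sum(!keep)
  if (verbose && any(!keep))
    message(sum(!keep), " dot(s) outside the evaluation region discarded")
  out
}
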