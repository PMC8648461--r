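#' Construct an elastogram image
#'
#' An `elastogram` bundles an 8-bit RGB raster with the binary region-of-
#' interest (ROI) mask delimiting cervix tissue, plus minimal metadata. All
#' color-fraction computations in the package are restricted to ROI pixels.
#'
#' @param pixels integer array `H x W x 3`, channel intensities in 0..255.
#' @param roi logical (or 0/1) matrix `H x W`; TRUE marks tissue pixels. Must
#'   contain at least one TRUE pixel.
#' @param patient_id optional string identifier.
#' @param timepoint `"pre"` or `"post"` (or NA).
#' @param seed integer seed the image was generated from, if any.
#' @param truth optional `H x W` integer matrix of ground-truth color labels
#'   (codes from [label_levels()]); attached by [generate_elastogram()].
#' @return an object of class `elastogram`.
#' @export
elastogram <- function(pixels, roi, patient_id = NA_character_,
                       timepoint = NA_character_, seed = NA_integer_,
                       truth = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  roi <- matrix(as.logical(roi), nrow = nrow(roi), ncol = ncol(roi))
  if (!identical(dim(roi), dim(pixels)[1:2])) {
    stop("`roi` and `pixels` must share H x W dimensions", call. = FALSE)
  }
  if (!any(roi)) stop("ROI mask must contain at least one tissue pixel",
                      call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in 0..255", call. = FALSE)
  }
  if (!is.na(timepoint) && !timepoint %in% c("pre", "post")) {
    stop('`timepoint` must be "pre" or "post"', call. = FALSE)
  }
  structure(
    list(pixels = array(as.integer(round(pixels)), dim = dim(pixels)),
         roi = roi,
         meta = list(patient_id = patient_id, timepoint = timepoint,
                     seed = seed),
         truth = truth),
    class = "elastogram")
}

#' @export
print.elastogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<elastogram> %d x %d px, %d ROI px", d[1], d[2], sum(x$roi)))
  if (!is.na(x$meta$patient_id)) {
    cat(sprintf("  [%s/%s]", x$meta$patient_id, x$meta$timepoint))
  }
  cat("\n")
  invisible(x)
}

#' Write / read an elastogram as a PNG pair
#'
#' The raster is written as an 8-bit RGB PNG and the ROI mask as a sibling
#' single-channel PNG holding 0/255. `read_elastogram()` reverses the pair.
#'
#' @param img an [elastogram()].
#' @param path output path for the RGB PNG; the mask is written next to it
#'   with suffix `_mask.png` unless `mask_path` is given.
#' @param mask_path optional explicit path for the mask PNG.
#' @return `write_elastogram()` returns the two paths invisibly;
#'   `read_elastogram()` returns an [elastogram()].
#' @export
write_elastogram <- function(img, path, mask_path = NULL) {
  stopifnot(inherits(img, "elastogram"))
  if (is.null(mask_path)) mask_path <- sub("\\.png$", "_mask.png", path)
  png::writePNG(img$pixels / 255, target = path)
  png::writePNG(matrix(ifelse(img$roi, 1, 0), nrow(img$roi)), target = mask_path)
  invisible(c(image = path, mask = mask_path))
}

#' @rdname write_elastogram
#' @export
read_elastogram <- function(path, mask_path = NULL) {
  if (is.null(mask_path)) mask_path <- sub("\\.png$", "_mask.png", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  elastogram(round(px * 255), m > 0.5)
}
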