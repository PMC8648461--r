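#' Label levels used by the pixel classifier
#'
#' Integer codes 1..5 for `blue`, `green`, `red`, `other`, `background`.
#' Background is reserved for pixels outside the ROI mask.
#'
#' @return character vector of the five level names in code order.
#' @export
label_levels <- function() c("blue", "green", "red", "other", "background")

#' Classify every ROI pixel by hue
#'
#' Maps each tissue pixel of a color-coded elastogram to one of the rubric's
#' color classes with a fixed hue/saturation/value rule: pixels with
#' saturation < 0.2 or value < 0.15 are `other` (too desaturated or dark to
#' read as a stiffness color); otherwise hue in \[210, 270\] degrees is
#' `blue`, \[90, 150\] is `green`, \[-20, 20\] (i.e. >= 340 or <= 20) is
#' `red`, and any remaining hue is `other`. Pixels outside the ROI are
#' `background`. The rule is deterministic — it is the quantitative stand-in
#' for a reader judging "the blue area" by eye.
#'
#' An optional 3x3 median filter per channel can be applied before
#' classification (`median_filter = TRUE`); the default applies the
#' per-pixel rule exactly as stated.
#'
#' @param img an [elastogram()].
#' @param median_filter logical; smooth each channel with a 3x3 median
#'   before classifying. Default FALSE.
#' @return a `label_map`: an `H x W` integer matrix with codes indexing
#'   [label_levels()], `background` exactly where the ROI mask is 0.
#' @export
classify_pixels <- function(img, median_filter = FALSE) {
  stopifnot(inherits(img, "elastogram"))
  if (!any(img$roi)) stop("empty ROI", call. = FALSE)
  px <- img$pixels
  if (median_filter) for (ch in 1:3) px[, , ch] <- median3x3(px[, , ch])
  idx <- which(img$roi)
  r <- px[, , 1][idx]; g <- px[, , 2][idx]; b <- px[, , 3][idx]
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  hue <- hsv[1, ] * 360; sat <- hsv[2, ]; val <- hsv[3, ]
  lab <- rep(4L, length(idx))                       # other
  chromatic <- sat >= 0.2 & val >= 0.15
  lab[chromatic & hue >= 210 & hue <= 270] <- 1L    # blue
  lab[chromatic & hue >= 90 & hue <= 150] <- 2L     # green
  lab[chromatic & (hue >= 340 | hue <= 20)] <- 3L   # red
  lab[!chromatic] <- 4L
  labels <- matrix(5L, nrow(img$roi), ncol(img$roi))
  labels[idx] <- lab
  structure(labels, class = "label_map")
}

# 3x3 median filter with edge replication.
median3x3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  stack <- vapply(1:9, function(k) {
    dy <- (k - 1) %% 3; dx <- (k - 1) %/% 3
    pad[dy + 1:h, dx + 1:w]
  }, matrix(0, h, w))
  apply(stack, c(1, 2), stats::median)
}

#' Area fractions of a label map
#'
#' Counts ROI pixels per color class and converts the integer counts to
#' fractions of the ROI pixel total (never the whole frame), the quantity
#' the 1-5 rubric thresholds. Counts over the four classes always partition
#' the ROI, so the fractions sum to 1.
#'
#' @param labels a `label_map` from [classify_pixels()].
#' @return a [color_composition()].
#' @export
compute_composition <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  counts <- tabulate(labels[labels != 5L], nbins = 4L)
  total <- sum(counts)
  if (total < 1L) stop("label map has no ROI pixels", call. = FALSE)
  color_composition(counts[1] / total, counts[2] / total, counts[3] / total,
                    counts[4] / total)
}

#' Write a label map as an indexed PNG
#'
#' Encodes the five label codes as fixed gray levels (blue=50, green=100,
#' red=150, other=200, background=0) in a single-channel PNG;
#' `read_label_map()` reverses the coding.
#'
#' @param labels a `label_map`.
#' @param path output PNG path.
#' @return the path, invisibly; `read_label_map()` returns a `label_map`.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  codes <- c(50, 100, 150, 200, 0) / 255
  png::writePNG(matrix(codes[unclass(labels)], nrow(labels)), target = path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lut <- c(`50` = 1L, `100` = 2L, `150` = 3L, `200` = 4L, `0` = 5L)
  lab <- lut[as.character(m)]
  if (anyNA(lab)) stop("not an elastoscore label-map PNG", call. = FALSE)
  structure(matrix(lab, nrow(m)), class = "label_map")
}
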