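#' Color composition of an elastogram region of interest
#'
#' A `color_composition` holds the fractions of ROI (cervix tissue) pixels
#' classified as blue, green, red, and other. Blue encodes hard tissue, red
#' soft tissue, green intermediate elasticity; "other" collects desaturated,
#' dark, or off-palette pixels. Fractions are defined over ROI pixels only,
#' never the whole frame, and must sum to 1.
#'
#' @param f_blue,f_green,f_red,f_other fractions in \[0, 1\] summing to 1
#'   (within 1e-9). `f_other` defaults to the complement of the first three.
#' @return an object of class `color_composition`: a named numeric vector
#'   with elements `f_blue`, `f_green`, `f_red`, `f_other`.
#' @examples
#' color_composition(0.6, 0.4, 0)
#' color_composition(0.4, 0.35, 0.25)
#' @export
color_composition <- function(f_blue, f_green, f_red, f_other = NULL) {
  if (is.null(f_other)) f_other <- 1 - f_blue - f_green - f_red
  x <- c(f_blue = f_blue, f_green = f_green, f_red = f_red, f_other = f_other)
  if (length(x) != 4L || !is.numeric(x) || anyNA(x)) {
    stop("composition must be four finite numeric fractions", call. = FALSE)
  }
  # tolerate tiny negative round-off from the complement
  x[abs(x) < 1e-12] <- 0
  if (any(x < 0) || any(x > 1)) {
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("composition fractions must sum to 1 (within 1e-9), got ",
         format(sum(x), digits = 12), call. = FALSE)
  }
  structure(x, class = "color_composition")
}

#' @export
print.color_composition <- function(x, ...) {
  cat("<color_composition>  blue =", sprintf("%.4f", x[["f_blue"]]),
      " green =", sprintf("%.4f", x[["f_green"]]),
      " red =", sprintf("%.4f", x[["f_red"]]),
      " other =", sprintf("%.4f", x[["f_other"]]), "\n")
  invisible(x)
}

is_composition <- function(x) inherits(x, "color_composition")

as_composition <- function(x) {
  if (is_composition(x)) return(x)
  x <- as.numeric(x)
  if (length(x) == 3L) x <- c(x, 1 - sum(x))
  color_composition(x[1], x[2], x[3], x[4])
}
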