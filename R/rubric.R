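#' Elasticity score (1-5) from a color composition
#'
#' Implements the blue/green/red area-fraction rubric used to grade cervical
#' strain elastograms. With blue encoding hard tissue, the grade rises with
#' the blue area fraction of the cervix ROI:
#'
#' \itemize{
#'   \item 1 — blue, green and red all visible, blue area <= 50\%
#'   \item 2 — blue and green alternate with no red, blue area <= 50\%
#'   \item 3 — no red, blue area in (50\%, 70\%\]
#'   \item 4 — mainly blue, no red, blue area > 70\%
#'   \item 5 — the whole ROI uniformly blue
#' }
#'
#' Rules are evaluated in precedence order 5 -> 4 -> 3 -> 2 -> 1, which
#' resolves the overlapping printed interval endpoints ("<= 50\%" vs
#' "50\%-70\%") with half-open intervals. A color counts as *visible* when
#' its fraction is at least `visibility_threshold`; *uniform blue* means
#' `f_blue >= uniform_threshold` (strict equality to 1 never survives noise).
#' Compositions no printed rule covers are still scored: red visible with
#' blue > 50\% scores by the blue interval alone (blue dominates the rubric),
#' and a degenerate ROI with blue <= 50\% and neither red nor green visible
#' scores 1.
#'
#' @param comp a [color_composition()] (or a length-4 fraction vector).
#' @param visibility_threshold minimum ROI fraction for a color to count as
#'   visible; default 0.01.
#' @param uniform_threshold minimum blue fraction for "uniform blue";
#'   default 0.95.
#' @return integer score in 1..5.
#' @examples
#' score_composition(color_composition(0.40, 0.35, 0.25)) # 1
#' score_composition(color_composition(0.60, 0.40, 0.00)) # 3
#' score_composition(color_composition(1.00, 0.00, 0.00)) # 5
#' @export
score_composition <- function(comp, visibility_threshold = 0.01,
                              uniform_threshold = 0.95) {
  if (visibility_threshold <= 0 || visibility_threshold >= 1 ||
      uniform_threshold <= 0 || uniform_threshold >= 1) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  comp <- as_composition(comp)
  b <- comp[["f_blue"]]; g <- comp[["f_green"]]; r <- comp[["f_red"]]
  if (b >= uniform_threshold) return(5L)
  if (b > 0.7) return(4L)
  if (b > 0.5) return(3L)
  if (r >= visibility_threshold) return(1L)
  if (g >= visibility_threshold) return(2L)
  1L
}

#' Elasticity score of an elastogram image
#'
#' Full image path: classify every ROI pixel by hue, measure the blue/green/
#' red/other area fractions, and apply the 1-5 rubric.
#'
#' @param img an [elastogram()] image.
#' @inheritParams score_composition
#' @return integer score in 1..5.
#' @seealso [classify_pixels()], [compute_composition()], [score_composition()]
#' @export
score_image <- function(img, visibility_threshold = 0.01,
                        uniform_threshold = 0.95) {
  score_composition(compute_composition(classify_pixels(img)),
                    visibility_threshold = visibility_threshold,
                    uniform_threshold = uniform_threshold)
}
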