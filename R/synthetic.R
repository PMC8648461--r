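#' Canonical palette of the synthetic elastogram generator
#'
#' Pure pre-noise colors for the four tissue classes and the background:
#' blue (0,0,255) hard tissue, green (0,255,0) intermediate, red (255,0,0)
#' soft, other (128,128,0) off-palette, background (10,10,10) near-black.
#' The palette is maximally separable under the hue classifier of
#' [classify_pixels()].
#'
#' @return a 5 x 3 integer matrix with rownames
#'   `blue`, `green`, `red`, `other`, `background`.
#' @export
elasto_palette <- function() {
  rbind(blue = c(0L, 0L, 255L), green = c(0L, 255L, 0L),
        red = c(255L, 0L, 0L), other = c(128L, 128L, 0L),
        background = c(10L, 10L, 10L))
}

#' Sample a color composition that grades to a given score
#'
#' Inverse of the 1-5 rubric: draws a [color_composition()] uniformly within
#' the admissible region of the requested score, so that
#' `score_composition(composition_for_score(s))` is `s` for every seed.
#' Regions (half-open, matching rubric precedence): score 1 has red and green
#' visible with blue in (0.01, 0.5\]; score 2 has no red, green visible, blue
#' in (0.01, 0.5\]; score 3 has no red, blue in (0.5, 0.7\]; score 4 has no
#' red, blue in (0.7, 0.95); score 5 is uniform blue — the unique boundary
#' case (1, 0, 0, 0). Sampling stays 0.005 away from the blue interval
#' endpoints so pixel-level rounding in [generate_elastogram()] can never
#' flip the grade of a rendered image.
#'
#' @param score integer in 1..5.
#' @param rng_seed integer seed.
#' @return a [color_composition()].
#' @export
composition_for_score <- function(score, rng_seed = 1L) {
  if (length(score) != 1L || !score %in% 1:5) {
    stop("`score` must be a single integer in 1..5", call. = FALSE)
  }
  score <- as.integer(score)
  with_seed(rng_seed, {
    if (score == 5L) return(color_composition(1, 0, 0, 0))
    if (score == 4L) {
      b <- runif(1, 0.705, 0.945)
      g <- (1 - b) * runif(1, 0.6, 1)
      return(color_composition(b, g, 0, 1 - b - g))
    }
    if (score == 3L) {
      b <- runif(1, 0.505, 0.695)
      g <- (1 - b) * runif(1, 0.4, 1)
      return(color_composition(b, g, 0, 1 - b - g))
    }
    b <- runif(1, 0.02, 0.495)
    rem <- 1 - b
    if (score == 2L) {
      g <- rem * runif(1, 0.4, 1)
      return(color_composition(b, g, 0, rem - g))
    }
    r <- rem * runif(1, 0.1, 0.5)           # red clearly visible
    g <- (rem - r) * runif(1, 0.4, 1)       # green clearly visible
    color_composition(b, g, r, rem - r - g)
  })
}

# Integer pixel quotas for the four colors over n ROI pixels
# (largest-remainder rounding: quotas sum to n exactly).
color_quotas <- function(comp, n) {
  f <- as.numeric(comp)
  raw <- f * n
  q <- floor(raw)
  left <- n - sum(q)
  if (left > 0) {
    take <- order(raw - q, decreasing = TRUE)[seq_len(left)]
    q[take] <- q[take] + 1
  }
  stats::setNames(as.integer(q), c("blue", "green", "red", "other"))
}

#' Generate a synthetic color-coded elastogram
#'
#' Emulates a cervical strain elastogram: an elliptical cervix ROI inscribed
#' at 80\% of the frame, tiled with contiguous blue/green/red/other blobs
#' whose ROI area fractions match `comp` exactly at the pixel level
#' (largest-remainder rounding), over a near-black background. Blobs are
#' grown from one random seed pixel per color by claiming unassigned ROI
#' pixels in order of distance from the seed (colors visited in random
#' order), then i.i.d. Gaussian channel noise of standard deviation
#' `noise_sd` is added to ROI pixels and clipped to 0..255. The generated
#' ground-truth label matrix is kept in the `truth` field. Identical seeds
#' and parameters yield bit-identical images.
#'
#' @param comp a [color_composition()] with the target area fractions.
#' @param height,width frame size in pixels, each at least 32.
#' @param noise_sd non-negative Gaussian channel-noise standard deviation
#'   (8-bit intensity units).
#' @param rng_seed integer seed.
#' @param patient_id,timepoint optional metadata stored on the image.
#' @return an [elastogram()].
#' @examples
#' img <- generate_elastogram(color_composition(0.6, 0.4, 0), 64, 64,
#'                            noise_sd = 0, rng_seed = 7)
#' score_image(img)  # 3
#' @export
generate_elastogram <- function(comp, height = 128L, width = 128L,
                                noise_sd = 0, rng_seed = 1L,
                                patient_id = NA_character_,
                                timepoint = NA_character_) {
  comp <- as_composition(comp)
  if (height < 32L || width < 32L) {
    stop("`height` and `width` must each be at least 32", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)

  h <- as.integer(height); w <- as.integer(width)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- 0.4 * h; rx <- 0.4 * w
  row_i <- matrix(seq_len(h), h, w)
  col_i <- matrix(seq_len(w), h, w, byrow = TRUE)
  roi <- ((row_i - cy) / ry)^2 + ((col_i - cx) / rx)^2 <= 1
  idx <- which(roi)                       # column-major linear indices
  n <- length(idx)
  q <- color_quotas(comp, n)

  labels <- matrix(5L, h, w)              # 5 = background
  with_seed(rng_seed, {
    active <- which(q > 0L)
    ord <- if (length(active) > 1L) sample(active) else active
    seeds <- idx[sample.int(n, length(ord))]
    free <- rep(TRUE, n)
    py <- row_i[idx]; px <- col_i[idx]
    for (k in seq_along(ord)) {
      color <- ord[k]
      sy <- row_i[seeds[k]]; sx <- col_i[seeds[k]]
      cand <- which(free)
      d2 <- (py[cand] - sy)^2 + (px[cand] - sx)^2
      take <- cand[order(d2)[seq_len(q[color])]]
      labels[idx[take]] <- color
      free[take] <- FALSE
    }
    pal <- elasto_palette()
    px3 <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      plane <- matrix(pal["background", ch], h, w)
      plane[idx] <- pal[labels[idx], ch]
      if (noise_sd > 0) {
        plane[idx] <- plane[idx] + stats::rnorm(n, 0, noise_sd)
      }
      px3[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    elastogram(px3, roi, patient_id = patient_id, timepoint = timepoint,
               seed = as.integer(rng_seed), truth = labels)
  })
}
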