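#' Circle offsets of the FAST test
#'
#' The 16 offsets of the radius-3 Bresenham circle, clockwise from
#' 12 o'clock, i.e. starting at `(0, -3)` with y pointing down.
#'
#' @return 16x2 integer matrix with columns `dx`, `dy`.
#' @export
circle_offsets <- function() {
  m <- cf_circle_offsets()
  colnames(m) <- c("dx", "dy")
  m
}

#' Sample the 16-pixel circle neighborhood around a pixel
#'
#' @param img Grayscale matrix.
#' @param x,y Center pixel, 1-based; must be at least 3 px from every
#'   border (`4 <= x <= width - 3`).
#' @return List with `values` (16 intensities, clockwise from 12 o'clock)
#'   and `center` (the center intensity).
#' @export
circle_neighborhood <- function(img, x, y) {
  w <- ncol(img); h <- nrow(img)
  if (x < 4 || x > w - 3 || y < 4 || y > h - 3) {
    stop("center (", x, ", ", y, ") is closer than 3 px to the image border")
  }
  off <- circle_offsets()
  vals <- img[cbind(y + off[, "dy"], x + off[, "dx"])]
  list(values = as.numeric(vals), center = as.numeric(img[y, x]))
}

#' Per-pixel adaptive FAST threshold
#'
#' The threshold associated with a circle neighborhood is
#' `t = delta * (sum(I) - max(I) - min(I)) / mean(I)`, clipped into
#' `clamp`. Dropping the extreme values guards against specular
#' highlights and noise spikes; dividing by the neighborhood mean makes
#' the threshold invariant to multiplicative illumination changes, so
#' bright near-field and dark far-field regions are thresholded on equal
#' terms. An all-black neighborhood returns `clamp[1]`.
#'
#' @param nb A neighborhood from [circle_neighborhood()] or a numeric
#'   vector of 16 intensities.
#' @param delta Global threshold scale (>= 0).
#' @param clamp Length-2 `(min, max)` clip range.
#' @param contrast If `TRUE`, evaluate the rule on the center contrasts
#'   `|I_i - center|` (requires `nb` to carry a center value).
#' @return The scalar threshold.
#' @export
#' @examples
#' adaptive_threshold(rep(100, 16), delta = 1, clamp = c(0, 255)) # 14
adaptive_threshold <- function(nb, delta = 1.0, clamp = c(5, 80),
                               contrast = FALSE) {
  stopifnot(delta >= 0, length(clamp) == 2L)
  if (is.list(nb)) {
    v <- nb$values
    cen <- nb$center
  } else {
    v <- as.numeric(nb)
    cen <- NULL
  }
  if (length(v) != 16L) stop("neighborhood must contain 16 values")
  if (contrast) {
    if (is.null(cen)) stop("contrast mode needs the center intensity")
    v <- abs(v - cen)
  }
  s <- sum(v)
  if (s <= 0) return(clamp[1])
  t <- delta * (s - max(v) - min(v)) / (s / 16)
  min(max(t, clamp[1]), clamp[2])
}

#' FAST segment test on one neighborhood
#'
#' A pixel is a corner when at least `arc_len` circularly contiguous
#' circle pixels are all brighter than `center + t` or all darker than
#' `center - t`. The response is the largest value, over maximal
#' qualifying runs, of `sum(|I_i - center| - t)` along the run; it is the
#' score used for non-maximum suppression.
#'
#' @param nb Neighborhood (list from [circle_neighborhood()] or 16-vector).
#' @param t Threshold (>= 0).
#' @param center Center intensity (ignored when `nb` is a list).
#' @param arc_len Required contiguous run length (default 12).
#' @return List with `is_corner` and `response`.
#' @export
segment_test <- function(nb, t, center = NULL, arc_len = 12L) {
  stopifnot(t >= 0)
  if (is.list(nb)) {
    v <- nb$values
    center <- nb$center
  } else {
    v <- as.numeric(nb)
    if (is.null(center)) stop("center intensity required")
  }
  if (length(v) != 16L) stop("neighborhood must contain 16 values")
  cf_segment_test(v, center, t, as.integer(arc_len))
}

#' Detect keypoints with the adaptive-threshold FAST detector
#'
#' Runs the segment test at every interior pixel of every pyramid level,
#' each pixel with its own adaptive threshold (see [adaptive_threshold()]),
#' followed by 3x3 non-maximum suppression on the response within each
#' level. Keypoints carry level-local coordinates plus base-image
#' coordinates for matching across levels.
#'
#' @param x An `image_pyramid` or a grayscale matrix (a pyramid is built
#'   with the configured levels/factor/sigma).
#' @param config A [pipeline_config()].
#' @return Tibble with columns `x, y, level, response, threshold, angle,
#'   base_x, base_y`, ordered by level, then y, then x. `angle` is `NA`
#'   until descriptors are computed.
#' @export
#' @examples
#' img <- synth_image("checkerboard", size = c(64, 64))
#' detect_keypoints(img, pipeline_config(pyramid_levels = 2))
detect_keypoints <- function(x, config = pipeline_config()) {
  validate_config(config)
  pyr <- if (inherits(x, "image_pyramid")) {
    x
  } else {
    build_pyramid(x, config$pyramid_levels, config$pyramid_factor,
                  config$pyramid_sigma)
  }
  per_level <- lapply(seq_along(pyr$levels), function(k) {
    m <- cf_detect_level(
      pyr$levels[[k]],
      config$delta, config$threshold_clamp[1], config$threshold_clamp[2],
      config$fast_arc_length, config$contrast_mode,
      config$threshold_mode == "fixed", config$fixed_threshold,
      config$nms_enabled
    )
    tibble(
      x = m[, 1], y = m[, 2], level = k - 1L,
      response = m[, 3], threshold = m[, 4]
    )
  })
  kps <- dplyr::bind_rows(per_level)
  kps$angle <- NA_real_
  kps <- to_base_coords(kps, pyr$factor)
  kps[order(kps$level, kps$y, kps$x), ]
}
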