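#' Build a Gaussian scale-space pyramid
#'
#' Level 0 is the unmodified input. Each subsequent level is the previous
#' one blurred with a Gaussian (`sigma`, kernel truncated at 3 sigma,
#' reflected borders) and downsampled by `factor` with bilinear resampling
#' and floor-rounded dimensions. Detection runs on every level so the same
#' structure is found across scales.
#'
#' @param img Grayscale matrix (see [read_gray()]); at least 16x16 at the
#'   top level.
#' @param levels Number of levels (default 8).
#' @param factor Downsampling ratio between levels (default 1.5).
#' @param sigma Blur scale applied before each downsample (default 1.0).
#' @return An `image_pyramid`: list with `levels` (list of matrices),
#'   `factor`, `sigma` and `scales` (`factor^k` per level).
#' @export
#' @examples
#' pyr <- build_pyramid(matrix(128, 64, 64), levels = 3)
#' vapply(pyr$levels, ncol, 1L)
build_pyramid <- function(img, levels = 8L, factor = 1.5, sigma = 1.0) {
  stopifnot(is.matrix(img), levels >= 1L, factor > 1)
  # feasibility: every level must remain >= 16 px on both sides
  w <- ncol(img); h <- nrow(img); feasible <- 1L
  while (TRUE) {
    w2 <- floor(w / factor); h2 <- floor(h / factor)
    if (w2 < 16L || h2 < 16L) break
    feasible <- feasible + 1L
    w <- w2; h <- h2
  }
  if (min(dim(img)) < 16L) {
    stop("image must be at least 16x16")
  }
  if (levels > feasible) {
    stop("pyramid would shrink below 16x16: at most ", feasible,
         " level(s) feasible for a ", nrow(img), "x", ncol(img), " image")
  }
  lv <- vector("list", levels)
  lv[[1]] <- img
  for (k in seq_len(levels - 1L)) {
    prev <- lv[[k]]
    blurred <- cf_gaussian_blur(prev, sigma)
    lv[[k + 1]] <- cf_resize_bilinear(
      blurred,
      floor(nrow(prev) / factor),
      floor(ncol(prev) / factor)
    )
  }
  structure(
    list(levels = lv, factor = factor, sigma = sigma,
         scales = factor^(seq_len(levels) - 1L)),
    class = "image_pyramid"
  )
}

#' @export
print.image_pyramid <- function(x, ...) {
  dims <- vapply(x$levels, function(m) paste0(nrow(m), "x", ncol(m)), "")
  cat("<image_pyramid> ", length(x$levels), " levels, factor ", x$factor,
      "\n  ", paste(dims, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Map level-local keypoint coordinates to base-image pixels
#'
#' A keypoint at `(x, y)` on pyramid level `k` corresponds to
#' `(x0 * factor^k, y0 * factor^k)` in the base image (computed on the
#' 0-based pixel grid, returned 1-based), inverting the downsampling chain.
#'
#' @param kps Keypoint tibble with columns `x`, `y`, `level`.
#' @param factor Pyramid downsampling factor used at detection time.
#' @return The tibble with `base_x`, `base_y` columns added (or replaced).
#' @export
to_base_coords <- function(kps, factor = 1.5) {
  s <- factor^kps$level
  kps$base_x <- (kps$x - 1) * s + 1
  kps$base_y <- (kps$y - 1) * s + 1
  kps
}
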