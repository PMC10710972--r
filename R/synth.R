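#' Generate a synthetic test image
#'
#' Seeded generators emulating the imaging conditions of capsule
#' endoscopy frames without external data:
#'
#' * `"texture"` -- band-limited value noise (bilinear-upsampled random
#'   grids at three octaves) plus scattered soft blobs of varying radius
#'   and polarity, giving several hundred corner detections on a 320x320
#'   frame;
#' * `"endoscopy"` -- low-amplitude texture multiplied by a radial
#'   illumination profile (bright center, dark periphery, as produced by
#'   the capsule's on-board light source), hard-saturated specular
#'   highlight blobs near the bright field, and scattered small mucosal
#'   features whose local contrast is strong under full illumination but
#'   falls below the conventional fixed FAST threshold (t = 20) in the
#'   periphery -- the regime a per-pixel adaptive threshold is meant to
#'   recover;
#' * `"checkerboard"` -- 16 px squares, a dense ideal-corner pattern;
#' * `"blank"` -- constant 128.
#'
#' The same arguments produce a bit-identical image on every run.
#'
#' @param kind One of `"texture"`, `"endoscopy"`, `"checkerboard"`,
#'   `"blank"`.
#' @param size `c(height, width)` in pixels, each >= 32.
#' @param seed Integer seed for the texture noise.
#' @param illumination `c(center_gain, edge_gain)` of the radial falloff
#'   (endoscopy kind; edge gain must be below center gain).
#' @param specular Number of saturated specular blobs (endoscopy kind).
#' @param specular_radius Blob radius in pixels.
#' @param texture_amplitude Peak texture contrast in intensity units.
#' @return Grayscale matrix with integer intensities in `[0, 255]`.
#' @export
#' @examples
#' img <- synth_image("endoscopy", size = c(64, 64), seed = 3)
#' range(img)
synth_image <- function(kind = c("texture", "endoscopy", "checkerboard", "blank"),
                        size = c(320, 320), seed = 1L,
                        illumination = c(1.0, 0.3),
                        specular = 4L, specular_radius = 9,
                        texture_amplitude = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(size) == 2L, all(size >= 32L))
  h <- as.integer(size[1]); w <- as.integer(size[2])

  if (kind == "blank") {
    return(matrix(128, h, w))
  }
  if (kind == "checkerboard") {
    # small 3x3 bright squares at the centers of alternating 16-px cells.
    # A 12-of-16 segment test cannot fire on large-square corners at all
    # (an ideal 90-degree junction puts 5 circle pixels inside the shape,
    # capping the outside run at 11), so the dense ideal-corner pattern is
    # a checker lattice of marks smaller than the test circle: every mark
    # pixel sees all 16 circle pixels on the background
    sq <- 16L
    img <- matrix(30, h, w)
    cyc <- seq(1L, h - sq, by = sq)
    cxc <- seq(1L, w - sq, by = sq)
    for (i in seq_along(cyc)) {
      for (j in seq_along(cxc)) {
        if ((i + j) %% 2L == 0L) {
          y0 <- cyc[i] + sq %/% 2L
          x0 <- cxc[j] + sq %/% 2L
          img[y0 + (-1:1), x0 + (-1:1)] <- 225
        }
      }
    }
    return(img)
  }

  amp <- if (!is.null(texture_amplitude)) {
    texture_amplitude
  } else if (kind == "texture") {
    70
  } else {
    28
  }
  noise <- value_noise(h, w, seed)

  if (kind == "texture") {
    img <- 128 + amp * noise
    img <- add_blobs(img, seed, density = 0.0012, amp_range = c(30, 80) * amp / 70)
  } else {
    stopifnot(illumination[2] < illumination[1])
    # smooth mucosal background (coarser noise than the texture kind, so
    # the planted features dominate the local contrast)
    base <- 165 + amp * value_noise(h, w, seed, octaves = 2L, base_cell = 24)
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    rmax <- min(w, h) / 2
    r <- sqrt(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)) / rmax
    gain <- illumination[1] - (illumination[1] - illumination[2]) * pmin(r, 1)
    img <- round_half_up(pmin(pmax(base * gain, 0), 255))
    if (specular >= 1L) {
      # highlights sit where the light source shines: the bright field
      blobs <- withr::with_seed(as.integer(seed) + 1000L, {
        ang <- runif(specular, 0, 2 * pi)
        rad <- sqrt(runif(specular)) * 0.5 * rmax
        data.frame(bx = cx + rad * cos(ang), by = cy + rad * sin(ang))
      })
      xs <- matrix(seq_len(w), h, w, byrow = TRUE)
      ys <- matrix(seq_len(h), h, w)
      for (b in seq_len(specular)) {
        d2 <- (xs - blobs$bx[b])^2 + (ys - blobs$by[b])^2
        spot <- 255 * exp(-d2 / (2 * (specular_radius / 2)^2))
        spot[d2 <= (specular_radius / 3)^2] <- 255  # hard saturation core
        img <- pmax(img, round_half_up(spot))
      }
    }
    img <- plant_features(img, seed, gain, density = 0.0012)
    return(pmin(img, 255))
  }
  round_half_up(pmin(pmax(img, 0), 255))
}

# Small mucosal features for the endoscopy fixture: 3x3 raised disks whose
# local contrast tracks the illumination (~45 * gain) in the bright field
# but floors at 17 intensity units in the periphery -- visible to a
# detector thresholding below ~17, invisible to fixed t = 20.
plant_features <- function(img, seed, gain, density) {
  h <- nrow(img); w <- ncol(img)
  n <- max(1L, round(density * h * w))
  p <- withr::with_seed(as.integer(seed) + 2000L, {
    data.frame(
      x = round(runif(n, 8, w - 8)),
      y = round(runif(n, 8, h - 8))
    )
  })
  for (b in seq_len(n)) {
    x0 <- p$x[b]; y0 <- p$y[b]
    g <- gain[y0, x0]
    delta <- if (45 * g >= 24) round(45 * g) else 17
    bg <- img[y0, x0]
    img[y0 + (-1:1), x0 + (-1:1)] <- min(bg + delta, 255)
  }
  img
}

# Scattered soft Gaussian blobs of random radius (1.5-6 px) and polarity:
# the small-scale structure (pits, villi, vessels crossing) that makes FAST
# circles fire. density = blobs per pixel.
add_blobs <- function(img, seed, density, amp_range) {
  h <- nrow(img); w <- ncol(img)
  n <- max(1L, round(density * h * w))
  p <- withr::with_seed(as.integer(seed) + 500L, {
    data.frame(
      x = runif(n, 1, w), y = runif(n, 1, h),
      r = runif(n, 1.5, 6),
      a = sample(c(-1, 1), n, replace = TRUE) * runif(n, amp_range[1], amp_range[2])
    )
  })
  for (b in seq_len(n)) {
    rad <- ceiling(2.5 * p$r[b])
    xs <- max(1, floor(p$x[b] - rad)):min(w, ceiling(p$x[b] + rad))
    ys <- max(1, floor(p$y[b] - rad)):min(h, ceiling(p$y[b] + rad))
    d2 <- outer((ys - p$y[b])^2, (xs - p$x[b])^2, `+`)
    img[ys, xs] <- img[ys, xs] + p$a[b] * exp(-d2 / (2 * (p$r[b] / 1.6)^2))
  }
  img
}

# Band-limited value noise in roughly [-1, 1]: random grids at cell sizes
# 16, 8 and 4 px, bilinear-upsampled and summed with geometrically
# decreasing weights.
value_noise <- function(h, w, seed, octaves = 3L, base_cell = 16) {
  acc <- matrix(0, h, w)
  wsum <- 0
  withr::with_seed(as.integer(seed), {
    for (o in seq_len(octaves)) {
      cell <- base_cell / 2^(o - 1)
      gh <- max(2L, ceiling(h / cell) + 1L)
      gw <- max(2L, ceiling(w / cell) + 1L)
      g <- matrix(runif(gh * gw, -1, 1), gh, gw)
      up <- cf_resize_bilinear(g, h, w)
      wt <- 0.55^(o - 1)
      acc <- acc + wt * up
      wsum <- wsum + wt
    }
  })
  acc / wsum
}

#' Homography helpers
#'
#' `rotation_homography()` rotates about the image center (1-based pixel
#' coordinates, positive angle rotating x towards y, i.e. clockwise on
#' screen with y down); `translation_homography()` shifts by `(tx, ty)`.
#'
#' @param theta_deg Rotation angle in degrees.
#' @param size Image size `c(height, width)` (defines the center).
#' @param tx,ty Translation in pixels.
#' @return A 3x3 homography matrix, `H[3,3] = 1`.
#' @export
rotation_homography <- function(theta_deg, size) {
  th <- theta_deg * pi / 180
  cx <- (size[2] + 1) / 2; cy <- (size[1] + 1) / 2
  Tc <- matrix(c(1, 0, cx, 0, 1, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Tc_inv <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  Tc %*% R %*% Tc_inv
}

#' @rdname rotation_homography
#' @export
translation_homography <- function(tx, ty) {
  matrix(c(1, 0, tx, 0, 1, ty, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Warp an image by a homography
#'
#' Inverse bilinear warping: each output pixel samples the source at
#' `H^{-1} (x, y, 1)`. Exposed borders are filled with the image mean to
#' avoid creating spurious high-contrast corners along the frame edge.
#'
#' @param img Grayscale matrix.
#' @param H Invertible 3x3 homography mapping source to output
#'   coordinates.
#' @param fill Border fill intensity (default: image mean).
#' @return List with `image` (warped matrix, same size) and `homography`
#'   (the exact ground-truth `H` used).
#' @export
warp_image <- function(img, H, fill = NULL) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  d <- det(H)
  if (!is.finite(d) || abs(d) < 1e-12) stop("homography is not invertible")
  if (is.null(fill)) fill <- mean(img)
  out <- cf_warp(img, solve(H), fill, nrow(img), ncol(img))
  list(image = out, homography = H)
}

#' Generate a drifting frame sequence with ground truth
#'
#' Frame 1 is the base image; frame k is the base warped by the (k-1)-fold
#' composition of a per-frame motion (rotation about the center plus
#' translation), emulating a slowly moving capsule camera. The returned
#' homographies compose exactly: `H[[k]] = M %*% H[[k-1]]`.
#'
#' @param n_frames Number of frames (>= 2).
#' @param rotation_deg Per-frame rotation in degrees.
#' @param shift_px Per-frame translation `c(tx, ty)` in pixels.
#' @param seed Texture seed (geometry is seed-independent).
#' @param kind,size Passed to [synth_image()].
#' @return List with `frames` (list of matrices) and `homographies`
#'   (list of 3x3 matrices; `H[[k]]` maps frame-1 coordinates to frame-k
#'   coordinates, `H[[1]]` = identity).
#' @export
make_sequence <- function(n_frames, rotation_deg = 2, shift_px = c(2, 0),
                          seed = 7L, kind = "texture", size = c(320, 320)) {
  stopifnot(n_frames >= 2L)
  base <- synth_image(kind, size = size, seed = seed)
  M <- translation_homography(shift_px[1], shift_px[2]) %*%
    rotation_homography(rotation_deg, size)
  H <- diag(3)
  frames <- vector("list", n_frames)
  homs <- vector("list", n_frames)
  fill <- mean(base)
  frames[[1]] <- base
  homs[[1]] <- diag(3)
  for (k in 2:n_frames) {
    H <- M %*% H
    homs[[k]] <- H
    frames[[k]] <- warp_image(base, H, fill = fill)$image
  }
  list(frames = frames, homographies = homs)
}
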