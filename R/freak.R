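#' Build the retinal sampling pattern
#'
#' 43 sampling points: seven concentric circles of six points each (60
#' degrees apart, alternate circles rotated by 30 degrees so receptive
#' fields interleave) plus the center. Circle radii decrease geometrically
#' from `scale` inward; each point's Gaussian smoothing sigma is half the
#' radius of its circle, so neighboring fields overlap like retinal
#' receptive fields. All 903 unordered point pairs are enumerated in
#' lexicographic order (i < j).
#'
#' @param scale Radius of the outermost circle, in pixels.
#' @param ratio Geometric ratio between consecutive circle radii.
#' @return A `freak_pattern`: list with `points` (tibble `dx, dy, sigma,
#'   ring`), `pairs` (903x2, 1-based indices), and `orientation_pairs`
#'   (the 21 diametrically opposed same-circle pairs used for orientation).
#' @export
freak_pattern <- function(scale = 15, ratio = 0.7) {
  stopifnot(scale > 0, ratio > 0, ratio < 1)
  rings <- lapply(0:6, function(k) {
    r <- scale * ratio^k
    # alternate rings offset by 30 degrees
    th <- (0:5) * (pi / 3) + (k %% 2) * (pi / 6)
    tibble(
      dx = r * cos(th), dy = r * sin(th),
      sigma = r / 2, ring = k
    )
  })
  center <- tibble(dx = 0, dy = 0,
                   sigma = scale * ratio^6 / 4, ring = 7L)
  points <- dplyr::bind_rows(c(rings, list(center)))

  n <- nrow(points) # 43
  pairs <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    cbind(i, (i + 1L):n)
  }))
  colnames(pairs) <- c("i", "j")

  # diametric pairs within each ring: point p and p + 3 (60 deg * 3 = 180)
  opairs <- do.call(rbind, lapply(0:6, function(k) {
    base <- k * 6L
    cbind(base + 1:3, base + 4:6)
  }))
  colnames(opairs) <- c("i", "j")

  structure(
    list(points = points, pairs = pairs, orientation_pairs = opairs,
         scale = scale, ratio = ratio),
    class = "freak_pattern"
  )
}

#' Gaussian receptive-field sample
#'
#' Intensity of one pattern point: the Gaussian-weighted mean (kernel
#' sigma = the point's sigma, truncated at 3 sigma) around the point's
#' offset rotated by `angle` about `(cx, cy)`; the Gaussian is evaluated
#' at each pixel's sub-pixel distance from the real-valued field center.
#'
#' @param img Grayscale matrix.
#' @param cx,cy Keypoint position (1-based pixel coordinates).
#' @param point A row of `freak_pattern()$points` (list or 1-row tibble
#'   with `dx`, `dy`, `sigma`).
#' @param angle Pattern rotation in radians.
#' @return The smoothed intensity, or `NA` if the sampling window leaves
#'   the image.
#' @export
smoothed_sample <- function(img, cx, cy, point, angle = 0) {
  v <- cf_smoothed_sample(img, cx, cy, point$dx[1], point$dy[1],
                          point$sigma[1], angle)
  v[1]
}

#' Sign comparison of a receptive-field pair
#'
#' Bit value of one descriptor pair: 1 when the first smoothed intensity
#' strictly exceeds the second, else 0.
#'
#' @param v1,v2 Smoothed intensities.
#' @return 0 or 1.
#' @export
compare_pair <- function(v1, v2) as.integer(v1 - v2 > 0)

#' Raw 903-bit descriptors for keypoints on one image
#'
#' For each keypoint: estimate orientation (unless `forced_angle` is
#' given), sample the 43 receptive fields with the pattern rotated to
#' that orientation, and emit one bit per pair (bit a = 1 iff the first
#' point of pair a is strictly brighter). Keypoints whose sampling
#' windows leave the image are dropped (`keep = FALSE`).
#'
#' @param img Grayscale matrix.
#' @param kps Keypoint tibble with level-local `x`, `y` for this image.
#' @param pattern A [freak_pattern()].
#' @param forced_angle Optional vector of orientations (radians), one per
#'   keypoint, bypassing orientation estimation.
#' @return List with `keep` (logical), `angle` (radians) and `bits`
#'   (n x 903 integer 0/1 matrix; rows of dropped keypoints are zero).
#' @export
freak_raw <- function(img, kps, pattern = freak_pattern(),
                      forced_angle = NULL) {
  pts <- as.matrix(pattern$points[, c("dx", "dy", "sigma")])
  cf_freak_batch(
    img, cbind(kps$x, kps$y), pts,
    pattern$pairs - 1L, pattern$orientation_pairs - 1L,
    if (is.null(forced_angle)) numeric(0) else as.numeric(forced_angle)
  )
}

#' Keypoint orientation from the retinal pattern
#'
#' Sum of smoothed-intensity differences over the 21 diametrically
#' opposed same-circle point pairs, each weighted by the pair's unit
#' direction; the orientation is the `atan2` of the summed vector, in
#' `(-pi, pi]`. A constant patch yields 0 by convention.
#'
#' @inheritParams freak_raw
#' @param x,y Keypoint position.
#' @return Orientation in radians, or `NA` if the pattern leaves the image.
#' @export
compute_orientation <- function(img, x, y, pattern = freak_pattern()) {
  r <- freak_raw(img, tibble(x = x, y = y), pattern)
  if (!r$keep[1]) return(NA_real_)
  r$angle[1]
}

# ---------------------------------------------------------------------------
# Pair selection: reduce 903 raw comparisons to the most informative bits.

#' Fit the descriptor pair selection
#'
#' Given a training matrix of raw 903-bit descriptors (rows = keypoints),
#' ranks columns by how close their mean is to 0.5 -- for binary columns
#' the variance is `m (1 - m)`, so ordering by `|mean - 0.5|` ascending is
#' the same as ordering variance descending (distance of variance from
#' 0.5, as maximum binary variance is 0.25) -- and keeps the top `bits`
#' columns. Ties break by original column index.
#'
#' @param raw_bits Integer 0/1 matrix with 903 columns and >= 2 rows.
#' @param bits Number of columns to keep (default 512).
#' @return A `freak_selection`: list with `columns` (ordered kept indices)
#'   and `means` (all 903 column means).
#' @export
fit_selection <- function(raw_bits, bits = 512L) {
  if (!is.matrix(raw_bits) || nrow(raw_bits) < 2L) {
    stop("need a matrix with at least 2 descriptor rows")
  }
  stopifnot(bits >= 1L, bits <= ncol(raw_bits))
  m <- colMeans(raw_bits)
  ord <- order(abs(m - 0.5), seq_along(m))
  structure(
    list(columns = as.integer(ord[seq_len(bits)]), means = as.numeric(m)),
    class = "freak_selection"
  )
}

#' Write / read a pair selection file
#'
#' Plain text: a `bits` line, the selected column indices (1-based, in
#' selection order) and the 903 raw column means.
#'
#' @param sel A `freak_selection`.
#' @param path File path.
#' @return `read_selection()` returns a `freak_selection`;
#'   `write_selection()` returns `path` invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "freak_selection"))
  lines <- c(
    paste0("bits\t", length(sel$columns)),
    paste0("index\t", sel$columns),
    paste0("mean\t", sprintf("%.8f", sel$means))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("selection file not found: ", path)
  lines <- readLines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(f, `[`, "", 1)
  val <- vapply(f, `[`, "", 2)
  nb <- as.integer(val[key == "bits"][1])
  idx <- as.integer(val[key == "index"])
  means <- as.numeric(val[key == "mean"])
  if (is.na(nb) || length(idx) != nb || anyNA(idx)) {
    stop("malformed selection file: ", path)
  }
  structure(list(columns = idx, means = means), class = "freak_selection")
}

# cache for the packaged default selection
.capfeat_env <- new.env(parent = emptyenv())

#' Packaged default pair selection
#'
#' A selection fitted once on several thousand keypoints detected on
#' seeded synthetic textured images and shipped with the package. Refit
#' with [fit_selection()] for a different image population.
#'
#' @return A `freak_selection`.
#' @export
default_selection <- function() {
  if (is.null(.capfeat_env$default_selection)) {
    path <- system.file("extdata", "freak_selection_default.tsv",
                        package = "capfeat", mustWork = TRUE)
    .capfeat_env$default_selection <- read_selection(path)
  }
  .capfeat_env$default_selection
}

#' Describe keypoints with the 512-bit retinal descriptor
#'
#' Per keypoint, at its own pyramid level: estimate orientation, build the
#' rotated raw 903-bit descriptor, then project onto the selected columns
#' in selection order. Keypoints whose sampling pattern leaves their level
#' image are dropped.
#'
#' @param pyr An `image_pyramid` (or base image matrix).
#' @param kps Keypoint tibble from [detect_keypoints()].
#' @param config A [pipeline_config()].
#' @param selection A `freak_selection`; defaults to the packaged one.
#' @param pattern Optional [freak_pattern()] override.
#' @return List of class `described_keypoints`: `keypoints` (tibble with
#'   `angle` filled and base coordinates), `descriptors` (n x bits 0/1
#'   integer matrix, rows aligned with keypoints) and `n_dropped`.
#' @export
describe_keypoints <- function(pyr, kps, config = pipeline_config(),
                               selection = NULL, pattern = NULL) {
  if (!inherits(pyr, "image_pyramid")) {
    pyr <- build_pyramid(pyr, config$pyramid_levels, config$pyramid_factor,
                         config$pyramid_sigma)
  }
  if (is.null(selection)) selection <- default_selection()
  if (is.null(pattern)) pattern <- freak_pattern(config$pattern_scale)
  cols <- selection$columns[seq_len(min(config$descriptor_bits,
                                        length(selection$columns)))]

  out_k <- list(); out_d <- list(); dropped <- 0L
  for (lev in sort(unique(kps$level))) {
    sub <- kps[kps$level == lev, ]
    r <- freak_raw(pyr$levels[[lev + 1L]], sub, pattern)
    keep <- r$keep
    dropped <- dropped + sum(!keep)
    if (!any(keep)) next
    sub <- sub[keep, ]
    sub$angle <- r$angle[keep]
    out_k[[length(out_k) + 1L]] <- sub
    out_d[[length(out_d) + 1L]] <- r$bits[keep, cols, drop = FALSE]
  }
  if (length(out_k)) {
    keypoints <- dplyr::bind_rows(out_k)
    descriptors <- do.call(rbind, out_d)
  } else {
    keypoints <- kps[0, ]
    descriptors <- matrix(integer(0), nrow = 0, ncol = length(cols))
  }
  structure(
    list(keypoints = keypoints, descriptors = descriptors,
         n_dropped = dropped),
    class = "described_keypoints"
  )
}

#' @export
print.described_keypoints <- function(x, ...) {
  cat("<described_keypoints> ", nrow(x$keypoints), " keypoints, ",
      ncol(x$descriptors), "-bit descriptors (", x$n_dropped,
      " dropped at borders)\n", sep = "")
  invisible(x)
}
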