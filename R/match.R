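#' Hamming distance between two binary descriptors
#'
#' @param d1,d2 Equal-length 0/1 vectors.
#' @return Count of differing bit positions.
#' @export
hamming_distance <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("descriptor lengths differ")
  sum(as.integer(d1) != as.integer(d2))
}

#' Brute-force nearest-neighbor matching by Hamming distance
#'
#' For every descriptor in `A`, the single nearest descriptor in `B`;
#' ties break toward the lowest B index. One-directional (no cross-check),
#' no ratio test: outlier control is delegated to the GMS and RANSAC
#' stages.
#'
#' @param desc_a,desc_b 0/1 integer matrices, one descriptor per row,
#'   equal column counts.
#' @return Match tibble with `index_a, index_b, hamming, passed_gms,
#'   passed_ransac` (flags `NA` until the later stages run).
#' @export
match_descriptors <- function(desc_a, desc_b) {
  m <- cf_hamming_match(desc_a, desc_b)
  if (nrow(m) == 0L) {
    return(tibble(
      index_a = integer(0), index_b = integer(0), hamming = integer(0),
      passed_gms = logical(0), passed_ransac = logical(0)
    ))
  }
  tibble(
    index_a = seq_len(nrow(m)), index_b = m[, 1], hamming = m[, 2],
    passed_gms = NA, passed_ransac = NA
  )
}

#' Grid-based motion statistics match filtering
#'
#' Both images are split into `grid x grid` cells. A match linking cell i
#' (image A) to cell j (image B) is supported by the other matches that
#' link the 3x3 neighborhood of i to the 3x3 neighborhood of j; true
#' correspondences accumulate support because nearby features move
#' together, while random mismatches do not. A match passes when its
#' support satisfies `S - 1 > alpha * sqrt(n_i)` (the match itself is not
#' its own evidence), with `n_i` the number of matches originating in
#' cell i's neighborhood, under the best of four half-cell grid offsets
#' (to avoid penalizing matches near cell boundaries).
#'
#' The full match table is returned with `passed_gms` set; no rows are
#' removed, so the filter is idempotent.
#'
#' @param matches Match tibble from [match_descriptors()].
#' @param kps_a,kps_b Keypoint tibbles aligned with the descriptor rows;
#'   base coordinates (`base_x`, `base_y`) are used.
#' @param size_a,size_b Image sizes as `c(height, width)`.
#' @param grid Cells per image side.
#' @param alpha Support threshold factor.
#' @return The match tibble with `passed_gms` filled.
#' @export
gms_filter <- function(matches, kps_a, kps_b, size_a, size_b,
                       grid = 20L, alpha = 0.75) {
  n <- nrow(matches)
  if (n == 0L) return(matches)
  xa <- kps_a$base_x[matches$index_a]; ya <- kps_a$base_y[matches$index_a]
  xb <- kps_b$base_x[matches$index_b]; yb <- kps_b$base_y[matches$index_b]
  g <- as.integer(grid)
  ncell <- g * g
  cw_a <- size_a[2] / g; ch_a <- size_a[1] / g
  cw_b <- size_b[2] / g; ch_b <- size_b[1] / g

  cell_of <- function(x, y, cw, ch, ox, oy) {
    ix <- pmin(pmax(floor((x - 1) / cw + ox), 0), g - 1)
    iy <- pmin(pmax(floor((y - 1) / ch + oy), 0), g - 1)
    as.integer(iy * g + ix + 1)
  }
  neighbors <- function(cell) {
    ix <- (cell - 1L) %% g; iy <- (cell - 1L) %/% g
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    jx <- ix + nb$dx; jy <- iy + nb$dy
    ok <- jx >= 0 & jx < g & jy >= 0 & jy < g
    as.integer(jy[ok] * g + jx[ok] + 1)
  }

  passed <- rep(FALSE, n)
  for (off in list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))) {
    ca <- cell_of(xa, ya, cw_a, ch_a, off[1], off[2])
    cb <- cell_of(xb, yb, cw_b, ch_b, off[1], off[2])
    # pair-count table and per-A-cell counts
    tab <- matrix(0L, ncell, ncell)
    for (m in seq_len(n)) tab[ca[m], cb[m]] <- tab[ca[m], cb[m]] + 1L
    acount <- tabulate(ca, nbins = ncell)

    nb_cache <- vector("list", ncell)
    get_nb <- function(c0) {
      if (is.null(nb_cache[[c0]])) nb_cache[[c0]] <<- neighbors(c0)
      nb_cache[[c0]]
    }
    seen <- new.env(parent = emptyenv())
    for (m in seq_len(n)) {
      key <- paste0(ca[m], "_", cb[m])
      dec <- seen[[key]]
      if (is.null(dec)) {
        na_nb <- get_nb(ca[m]); nb_nb <- get_nb(cb[m])
        S <- sum(tab[na_nb, nb_nb])
        n_i <- sum(acount[na_nb])
        dec <- (S - 1) > alpha * sqrt(n_i)
        seen[[key]] <- dec
      }
      if (dec) passed[m] <- TRUE
    }
  }
  matches$passed_gms <- passed
  matches
}

# ---------------------------------------------------------------------------
# Homography estimation (normalized DLT) and RANSAC verification.

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2). Returns the 3x3 similarity.
hartley_transform <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  d <- mean(sqrt((x - mx)^2 + (y - my)^2))
  s <- if (d > 0) sqrt(2) / d else 1
  matrix(c(s, 0, -s * mx, 0, s, -s * my, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Direct linear transform on >= 4 correspondences; maps (xa, ya) -> (xb, yb).
dlt_homography <- function(xa, ya, xb, yb) {
  Ta <- hartley_transform(xa, ya)
  Tb <- hartley_transform(xb, yb)
  na_x <- Ta[1, 1] * xa + Ta[1, 3]; na_y <- Ta[2, 2] * ya + Ta[2, 3]
  nb_x <- Tb[1, 1] * xb + Tb[1, 3]; nb_y <- Tb[2, 2] * yb + Tb[2, 3]
  n <- length(xa)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(na_x[i], na_y[i], 1)
    A[2 * i - 1, ] <- c(rep(0, 3), -X, nb_y[i] * X)
    A[2 * i, ] <- c(X, rep(0, 3), -nb_x[i] * X)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Tb) %*% Hn %*% Ta
  normalize_homography(H)
}

normalize_homography <- function(H) {
  if (abs(H[3, 3]) > .Machine$double.eps) H <- H / H[3, 3]
  H
}

apply_homography <- function(H, x, y) {
  X <- H[1, 1] * x + H[1, 2] * y + H[1, 3]
  Y <- H[2, 1] * x + H[2, 2] * y + H[2, 3]
  Z <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  cbind(X / Z, Y / Z)
}

symmetric_error <- function(H, xa, ya, xb, yb) {
  Hi <- solve(H)
  f <- apply_homography(H, xa, ya)
  b <- apply_homography(Hi, xb, yb)
  pmax(sqrt((f[, 1] - xb)^2 + (f[, 2] - yb)^2),
       sqrt((b[, 1] - xa)^2 + (b[, 2] - ya)^2))
}

collinear4 <- function(x, y, eps = 1e-6) {
  for (tri in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
    a <- tri[1]; b <- tri[2]; c0 <- tri[3]
    area <- abs((x[b] - x[a]) * (y[c0] - y[a]) - (x[c0] - x[a]) * (y[b] - y[a]))
    if (area < eps) return(TRUE)
  }
  FALSE
}

#' RANSAC homography verification of a match set
#'
#' Seeded RANSAC over 4-point normalized-DLT hypotheses on the
#' GMS-surviving matches; inliers are matches whose symmetric transfer
#' error is at most `reproj_px`. The best model is refit on all its
#' inliers by least squares and the flags recomputed under the refined
#' model. The iteration count adapts to the observed inlier ratio
#' (confidence `conf`) up to `max_iter`. Degenerate (collinear) samples
#' are redrawn, not fatal.
#'
#' @param matches Match tibble with `passed_gms` set (if all flags are
#'   `NA`, all matches are treated as candidates).
#' @param kps_a,kps_b Keypoint tibbles aligned with descriptor rows.
#' @param reproj_px Inlier tolerance in pixels.
#' @param conf Target confidence.
#' @param max_iter Iteration cap.
#' @param seed RNG seed; identical seeds give identical results.
#' @return List with `homography` (3x3, normalized so `H[3,3] = 1`) and
#'   `matches` (tibble with `passed_ransac` filled).
#' @export
ransac_homography <- function(matches, kps_a, kps_b, reproj_px = 3,
                              conf = 0.995, max_iter = 2000L, seed = 1L) {
  cand <- if (all(is.na(matches$passed_gms))) {
    rep(TRUE, nrow(matches))
  } else {
    matches$passed_gms %in% TRUE
  }
  idx <- which(cand)
  if (length(idx) < 4L) {
    stop("verification failed: need at least 4 candidate matches, have ",
         length(idx))
  }
  xa <- kps_a$base_x[matches$index_a[idx]]
  ya <- kps_a$base_y[matches$index_a[idx]]
  xb <- kps_b$base_x[matches$index_b[idx]]
  yb <- kps_b$base_y[matches$index_b[idx]]
  n <- length(idx)

  best_inl <- logical(n)
  best_count <- -1L
  withr::with_seed(seed, {
    need <- max_iter
    it <- 0L
    while (it < min(need, max_iter)) {
      it <- it + 1L
      s <- sample.int(n, 4L)
      if (collinear4(xa[s], ya[s]) || collinear4(xb[s], yb[s])) next
      H <- tryCatch(dlt_homography(xa[s], ya[s], xb[s], yb[s]),
                    error = function(e) NULL)
      if (is.null(H) || abs(det(H)) < 1e-12) next
      err <- tryCatch(symmetric_error(H, xa, ya, xb, yb),
                      error = function(e) NULL)
      if (is.null(err)) next
      inl <- err <= reproj_px
      if (sum(inl) > best_count) {
        best_count <- sum(inl)
        best_inl <- inl
        w <- best_count / n
        if (w > 0 && w < 1) {
          need <- ceiling(log(1 - conf) / log(1 - w^4))
        } else if (w >= 1) {
          need <- it
        }
      }
    }
  })

  if (best_count < 4L) {
    stop("verification failed: no homography with >= 4 inliers found")
  }
  keep <- best_inl
  H <- dlt_homography(xa[keep], ya[keep], xb[keep], yb[keep])
  err <- symmetric_error(H, xa, ya, xb, yb)
  final <- err <= reproj_px
  matches$passed_ransac <- FALSE
  matches$passed_ransac[idx[final]] <- TRUE
  # contract: ransac survivors are a subset of gms survivors
  matches$passed_ransac <- matches$passed_ransac & (matches$passed_gms %in% c(TRUE, NA))
  list(homography = H, matches = matches)
}

#' Full detection-to-verification matching pipeline
#'
#' Detect (adaptive FAST over the pyramid), describe (512-bit retinal
#' descriptor), match (brute-force Hamming), filter (grid motion
#' statistics) and verify (RANSAC homography) a pair of images. Matches
#' flagged `passed_ransac` are the verified ("correct") correspondences
#' used by the evaluation harnesses.
#'
#' @param img_a,img_b Grayscale matrices.
#' @param config A [pipeline_config()].
#' @param selection Optional `freak_selection` (defaults to the packaged
#'   one).
#' @return A `capfeat_match`: list with `keypoints_a`, `keypoints_b`
#'   (described keypoint tibbles), `matches`, `homography` (or `NULL`
#'   when verification was impossible), `counts` (per-stage tibble) and
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' img <- synth_image("texture", size = c(160, 160), seed = 1)
#' res <- match_images(img, img)
#' glance(res)
#' }
match_images <- function(img_a, img_b, config = pipeline_config(),
                         selection = NULL) {
  validate_config(config)
  pyr_a <- build_pyramid(img_a, config$pyramid_levels, config$pyramid_factor,
                         config$pyramid_sigma)
  pyr_b <- build_pyramid(img_b, config$pyramid_levels, config$pyramid_factor,
                         config$pyramid_sigma)
  kp_a <- detect_keypoints(pyr_a, config)
  kp_b <- detect_keypoints(pyr_b, config)
  de_a <- describe_keypoints(pyr_a, kp_a, config, selection)
  de_b <- describe_keypoints(pyr_b, kp_b, config, selection)

  empty <- function(stage_counts) {
    warning("matching produced no verifiable correspondences")
    structure(
      list(keypoints_a = de_a$keypoints, keypoints_b = de_b$keypoints,
           matches = tibble(index_a = integer(0), index_b = integer(0),
                            hamming = integer(0), passed_gms = logical(0),
                            passed_ransac = logical(0)),
           homography = NULL, counts = stage_counts, config = config),
      class = "capfeat_match"
    )
  }
  counts <- tibble(
    stage = c("detected_a", "detected_b", "described_a", "described_b"),
    count = c(nrow(kp_a), nrow(kp_b), nrow(de_a$keypoints), nrow(de_b$keypoints))
  )
  if (nrow(de_a$keypoints) == 0L || nrow(de_b$keypoints) == 0L) {
    return(empty(counts))
  }

  matches <- match_descriptors(de_a$descriptors, de_b$descriptors)
  matches <- gms_filter(matches, de_a$keypoints, de_b$keypoints,
                        dim(img_a), dim(img_b),
                        config$gms_grid, config$gms_alpha)
  counts <- dplyr::bind_rows(counts, tibble(
    stage = c("coarse", "gms"),
    count = c(nrow(matches), sum(matches$passed_gms))
  ))
  ver <- tryCatch(
    ransac_homography(matches, de_a$keypoints, de_b$keypoints,
                      config$ransac_reproj_px, config$ransac_conf,
                      config$ransac_max_iter, config$rng_seed),
    error = function(e) NULL
  )
  if (is.null(ver)) {
    out <- empty(counts)
    out$matches <- matches
    return(out)
  }
  counts <- dplyr::bind_rows(counts, tibble(
    stage = "ransac", count = sum(ver$matches$passed_ransac)
  ))
  structure(
    list(keypoints_a = de_a$keypoints, keypoints_b = de_b$keypoints,
         matches = ver$matches, homography = ver$homography,
         counts = counts, config = config),
    class = "capfeat_match"
  )
}

#' @export
print.capfeat_match <- function(x, ...) {
  cat("<capfeat_match>\n")
  print(x$counts)
  invisible(x)
}

#' Turn a match result into a tidy tibble
#'
#' `tidy()` returns the per-match table; `glance()` a one-row summary with
#' stage counts and the matching score (verified matches over the smaller
#' keypoint count).
#'
#' @param x A `capfeat_match`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.capfeat_match <- function(x, ...) x$matches

#' @rdname tidy.capfeat_match
#' @export
glance.capfeat_match <- function(x, ...) {
  n1 <- nrow(x$keypoints_a); n2 <- nrow(x$keypoints_b)
  cm <- sum(x$matches$passed_ransac %in% TRUE)
  tibble(
    n_keypoints_a = n1, n_keypoints_b = n2,
    n_coarse = nrow(x$matches),
    n_gms = sum(x$matches$passed_gms %in% TRUE),
    n_verified = cm,
    matching_score = if (min(n1, n2) >= 1) {
      matching_score(min(cm, n1, n2), n1, n2)
    } else {
      NA_real_
    }
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
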