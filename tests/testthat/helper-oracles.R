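# Independent reference implementations used as oracles. These mirror the
# documented contracts with plain R arithmetic and deliberately share no
# code with the package internals.

# radius-3 Bresenham circle, clockwise from 12 o'clock, written out by hand
ORACLE_DX <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
ORACLE_DY <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)

oracle_adaptive_threshold <- function(v, delta, cmin, cmax) {
  s <- sum(v)
  if (s <= 0) return(cmin)
  t <- delta * (s - max(v) - min(v)) / (s / 16)
  min(max(t, cmin), cmax)
}

# brute-force arc scan: enumerate maximal circular runs on each side
oracle_segment_test <- function(v, cen, t, arc_len = 12L) {
  best <- 0
  corner <- FALSE
  for (side in 1:2) {
    q <- if (side == 1) v - cen > t else cen - v > t
    if (all(q)) {
      corner <- TRUE
      best <- max(best, sum(abs(v - cen) - t))
      next
    }
    if (!any(q)) next
    qq <- c(q, q)
    for (s in 1:16) {
      prev <- if (s == 1) 16 else s - 1
      if (q[s] && !q[prev]) {
        len <- 0
        while (len < 16 && qq[s + len]) len <- len + 1
        if (len >= arc_len) {
          corner <- TRUE
          idx <- ((s - 1 + 0:(len - 1)) %% 16) + 1
          best <- max(best, sum(abs(v[idx] - cen) - t))
        }
      }
    }
  }
  list(is_corner = corner, response = best)
}

# Exhaustive per-pixel reference detector for one image (one pyramid
# level). Vectorized circle extraction, per-candidate run scoring, and the
# same documented NMS tie rule (latest in reading order wins a plateau).
oracle_detect_level <- function(img, delta = 1.0, clamp = c(5, 80),
                                arc_len = 12L, nms = TRUE,
                                fixed_t = NULL) {
  h <- nrow(img); w <- ncol(img)
  ys <- 4:(h - 3); xs <- 4:(w - 3)
  n <- length(ys) * length(xs)
  cen <- as.vector(img[ys, xs])
  V <- matrix(0, n, 16)
  for (k in 1:16) V[, k] <- as.vector(img[ys + ORACLE_DY[k], xs + ORACLE_DX[k]])

  if (is.null(fixed_t)) {
    s <- rowSums(V)
    tvec <- delta * (s - apply(V, 1, max) - apply(V, 1, min)) / (s / 16)
    tvec[s <= 0] <- clamp[1]
    tvec <- pmin(pmax(tvec, clamp[1]), clamp[2])
  } else {
    tvec <- rep(fixed_t, n)
  }

  resp <- numeric(n)
  bright <- V > cen + tvec
  dark <- V < cen - tvec
  # candidate pixels: any circular window of length arc_len fully set
  has_arc <- function(M) {
    MM <- cbind(M, M[, 1:(arc_len - 1), drop = FALSE])
    out <- rep(FALSE, nrow(M))
    for (s in 1:16) {
      out <- out | rowSums(MM[, s:(s + arc_len - 1), drop = FALSE]) == arc_len
    }
    out
  }
  cand <- which(has_arc(bright) | has_arc(dark))
  for (i in cand) {
    resp[i] <- oracle_segment_test(V[i, ], cen[i], tvec[i], arc_len)$response
  }
  R <- matrix(0, h, w)
  R[ys, xs] <- matrix(resp, length(ys), length(xs))
  TH <- matrix(0, h, w)
  TH[ys, xs] <- matrix(tvec, length(ys), length(xs))

  keep <- R > 0
  if (nms) {
    for (dy in -1:1) {
      for (dx in -1:1) {
        if (dx == 0 && dy == 0) next
        S <- matrix(0, h, w)
        ys2 <- max(1, 1 + dy):min(h, h + dy)
        xs2 <- max(1, 1 + dx):min(w, w + dx)
        S[ys2 - dy, xs2 - dx] <- R[ys2, xs2]
        later <- (dy > 0) || (dy == 0 && dx > 0)
        keep <- keep & if (later) R > S else R >= S
      }
    }
  }
  idx <- which(keep, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(
    x = idx[, 2], y = idx[, 1],
    response = R[idx], threshold = TH[idx]
  )
}

# random 16-value neighborhoods for threshold tests
random_neighborhoods <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) runif(16, 0, 255))
  })
}

# small deterministic test images
flat_image <- function(h = 32, w = 32, value = 100) matrix(value, h, w)

# one isolated high-contrast spot (all 16 circle pixels on the background)
spot_image <- function(h = 48, w = 48, x0 = 24, y0 = 24, bg = 50, fg = 250) {
  img <- matrix(bg, h, w)
  img[y0 + (-1:1), x0 + (-1:1)] <- fg
  img
}
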