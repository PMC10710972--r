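test_that("the retinal pattern has 43 points on 7 circles plus center, 903 pairs", {
  pat <- freak_pattern()
  expect_equal(nrow(pat$points), 43L)
  expect_equal(nrow(pat$pairs), 903L)
  expect_equal(nrow(pat$orientation_pairs), 21L)
  # each ring: 6 points, all pairwise angular gaps multiples of 60 degrees
  for (k in 0:6) {
    ring <- pat$points[pat$points$ring == k, ]
    expect_equal(nrow(ring), 6L)
    th <- sort(atan2(ring$dy, ring$dx) %% (2 * pi))
    gaps <- diff(th)
    expect_equal(gaps, rep(pi / 3, 5), tolerance = 1e-9)
    # sigma is half the ring radius
    r <- sqrt(ring$dx^2 + ring$dy^2)
    expect_equal(ring$sigma, r / 2, tolerance = 1e-9)
  }
  # radii decrease geometrically from the outermost circle
  radii <- vapply(0:6, function(k) {
    ring <- pat$points[pat$points$ring == k, ]
    sqrt(ring$dx[1]^2 + ring$dy[1]^2)
  }, 1.0)
  expect_equal(radii[1], pat$scale)
  expect_equal(radii[-1] / radii[-7], rep(pat$ratio, 6), tolerance = 1e-9)
  # center point carries the smallest sigma
  expect_lt(pat$points$sigma[43], min(pat$points$sigma[1:42]))
})

test_that("pattern geometry is homogeneous in scale", {
  p1 <- freak_pattern(scale = 10)
  p2 <- freak_pattern(scale = 20)
  expect_equal(p2$points$dx, 2 * p1$points$dx, tolerance = 1e-12)
  expect_equal(p2$points$sigma, 2 * p1$points$sigma, tolerance = 1e-12)
})

test_that("pairs are enumerated lexicographically with i < j", {
  pat <- freak_pattern()
  expect_true(all(pat$pairs[, 1] < pat$pairs[, 2]))
  expect_equal(pat$pairs[1, ], c(i = 1L, j = 2L))
  expect_equal(pat$pairs[903, ], c(i = 42L, j = 43L))
  expect_false(is.unsorted(order(pat$pairs[, 1], pat$pairs[, 2])))
})

test_that("receptive-field samples preserve constants and are periodic in angle", {
  img <- flat_image(64, 64, 100)
  pat <- freak_pattern(10)
  pt <- pat$points[1, ]
  expect_equal(smoothed_sample(img, 32, 32, pt, 0), 100, tolerance = 1e-9)
  expect_equal(smoothed_sample(img, 32, 32, pt, 1.3), 100, tolerance = 1e-9)
  # 2*pi-periodicity up to the discretization of the sampling window (the
  # sub-ulp angle residue can shift the integer window bounds by one row)
  v0 <- smoothed_sample(synth_image("texture", size = c(64, 64), seed = 1),
                        32, 32, pt, 0)
  v2 <- smoothed_sample(synth_image("texture", size = c(64, 64), seed = 1),
                        32, 32, pt, 2 * pi)
  expect_equal(v0, v2, tolerance = 5e-4)
})

test_that("a field straddling a step edge lies strictly between the plateaus", {
  step <- cbind(matrix(40, 64, 32), matrix(200, 64, 32))
  pt <- list(dx = 0, dy = 0, sigma = 3)
  v <- smoothed_sample(step, 32.5, 32, pt, 0)
  expect_gt(v, 40)
  expect_lt(v, 200)
  # independent weighted-sum oracle at the same location
  px <- 32.5; py <- 32; r <- ceiling(3 * 3)
  xs <- (floor(px) - r):(ceiling(px) + r)
  ys <- (py - r):(py + r)
  wgt <- outer(ys - py, xs - px, function(a, b) exp(-(a^2 + b^2) / (2 * 9)))
  expect_equal(v, sum(wgt * step[ys, xs]) / sum(wgt), tolerance = 1e-9)
})

test_that("pair comparison implements the strict sign rule", {
  expect_equal(compare_pair(120, 80), 1L)
  expect_equal(compare_pair(80, 120), 0L)
  expect_equal(compare_pair(100, 100), 0L)  # ties take the <= 0 branch
})

test_that("a constant patch has an all-zero raw descriptor and zero angle", {
  img <- flat_image(64, 64, 128)
  kps <- tibble::tibble(x = 32, y = 32)
  r <- freak_raw(img, kps, freak_pattern(10))
  expect_true(r$keep[1])
  expect_equal(r$angle[1], 0)
  expect_equal(sum(r$bits), 0L)
})

test_that("descriptors are deterministic and drop out-of-bounds keypoints", {
  img <- synth_image("texture", size = c(64, 64), seed = 2)
  kps <- tibble::tibble(x = c(32, 32, 5), y = c(32, 32, 5))
  r <- freak_raw(img, kps, freak_pattern(10))
  expect_true(r$keep[1] && r$keep[2])
  expect_false(r$keep[3])  # pattern exceeds the image near the border
  expect_identical(r$bits[1, ], r$bits[2, ])
})

test_that("raw descriptor bits equal sign comparisons of sampled fields", {
  img <- synth_image("texture", size = c(80, 80), seed = 4)
  pat <- freak_pattern(10)
  r <- freak_raw(img, tibble::tibble(x = 40, y = 40), pat,
                 forced_angle = 0)
  vals <- vapply(seq_len(43), function(i) {
    smoothed_sample(img, 40, 40, pat$points[i, ], 0)
  }, 1.0)
  want <- as.integer(vals[pat$pairs[, 1]] - vals[pat$pairs[, 2]] > 0)
  expect_identical(r$bits[1, ], want)
})

test_that("orientation follows the local gradient and tracks image rotation", {
  # ramp increasing along +x: orientation aligns with the x axis
  ramp <- matrix(rep(seq(0, 255, length.out = 101), each = 101), 101, 101)
  a <- compute_orientation(ramp, 51, 51)
  expect_lt(min(abs(a), abs(abs(a) - pi)), 0.05)

  img <- synth_image("texture", size = c(101, 101), seed = 2)
  a0 <- compute_orientation(img, 51, 51)
  rot <- warp_image(img, rotation_homography(90, dim(img)))$image
  a1 <- compute_orientation(rot, 51, 51)
  d <- (a1 - a0) %% (2 * pi)
  if (d > pi) d <- d - 2 * pi
  expect_equal(d, pi / 2, tolerance = 0.1)
})

test_that("pair selection ranks columns by |mean - 0.5| with index tie-breaks", {
  m <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))
  # means: 0.6, 0.0, 0.6 -> |m - 0.5|: 0.1, 0.5, 0.1 -> order 1, 3, 2
  sel <- fit_selection(m, 3L)
  expect_equal(sel$columns, c(1L, 3L, 2L))

  tied <- matrix(c(1, 0), 2, 5)  # every column mean 0.5
  expect_equal(fit_selection(tied, 5L)$columns, 1:5)

  set.seed(12)
  full <- fit_selection(matrix(sample(0:1, 40 * 903, replace = TRUE), 40, 903),
                        903L)
  expect_setequal(full$columns, 1:903)
  expect_error(fit_selection(matrix(0, 1, 10)), "at least 2")
})

test_that("mean ordering equals binary-variance ordering", {
  # exact integer keys: |mean - 0.5| is monotone in |2s - n| and the
  # variance s(n - s)/n^2 has |var - 0.5| monotone in -s(n - s), which
  # orders identically; floating-point keys agree up to last-ulp ties
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- 30L
      m <- matrix(rbinom(n * 60, 1, runif(1, 0.1, 0.9)), n, 60)
      s <- colSums(m)
      by_mean <- order(abs(2 * s - n), seq_along(s))
      by_var <- order(-(s * (n - s)), seq_along(s))
      expect_identical(by_mean, by_var)
      # fit_selection keeps exactly the columns with the smallest keys
      sel <- fit_selection(m, 20L)
      key <- abs(2 * s - n)
      expect_equal(sort(key[sel$columns]), sort(key)[1:20])
    }
  })
})

test_that("descriptors are invariant to global intensity gain", {
  img <- synth_image("texture", size = c(80, 80), seed = 6)
  pat <- freak_pattern(10)
  kps <- tibble::tibble(x = c(40, 35), y = c(40, 45))
  r1 <- freak_raw(img, kps, pat)
  r2 <- freak_raw(img * 0.5, kps, pat)
  expect_identical(r1$bits, r2$bits)
  expect_equal(r1$angle, r2$angle, tolerance = 1e-9)
})

test_that("describe_keypoints projects onto the selection and fills angles", {
  img <- synth_image("texture", size = c(128, 128), seed = 1)
  cfg <- pipeline_config(pyramid_levels = 2)
  pyr <- build_pyramid(img, 2, 1.5)
  kps <- detect_keypoints(pyr, cfg)
  de <- describe_keypoints(pyr, kps, cfg)
  expect_equal(ncol(de$descriptors), 512L)
  expect_equal(nrow(de$descriptors), nrow(de$keypoints))
  expect_true(all(!is.na(de$keypoints$angle)))
  expect_equal(nrow(de$keypoints) + de$n_dropped, nrow(kps))
  # empty input gives empty output
  de0 <- describe_keypoints(pyr, kps[0, ], cfg)
  expect_equal(nrow(de0$keypoints), 0L)
})

test_that("matched keypoints across a 10-degree rotation stay Hamming-close", {
  img <- synth_image("texture", seed = 1)
  cfg <- pipeline_config()
  H <- rotation_homography(10, dim(img))
  rot <- warp_image(img, H)$image
  pa <- build_pyramid(img, 8, 1.5)
  pb <- build_pyramid(rot, 8, 1.5)
  da <- describe_keypoints(pa, detect_keypoints(pa, cfg), cfg)
  db <- describe_keypoints(pb, detect_keypoints(pb, cfg), cfg)
  # ground-truth correspondences: nearest described keypoint within 2 px
  pxy <- cbind(da$keypoints$base_x, da$keypoints$base_y, 1) %*% t(H)
  pxy <- pxy[, 1:2] / pxy[, 3]
  true_h <- integer(0); rand_h <- integer(0)
  withr::with_seed(5, {
    for (i in seq_len(nrow(da$keypoints))) {
      d2 <- (db$keypoints$base_x - pxy[i, 1])^2 +
        (db$keypoints$base_y - pxy[i, 2])^2
      j <- which.min(d2)
      if (d2[j] < 4) {
        true_h <- c(true_h, hamming_distance(da$descriptors[i, ],
                                             db$descriptors[j, ]))
        rand_h <- c(rand_h, hamming_distance(da$descriptors[i, ],
                                             db$descriptors[sample.int(nrow(db$descriptors), 1), ]))
      }
    }
  })
  expect_gt(length(true_h), 50)
  expect_lt(stats::median(true_h), 0.25 * 512)
  expect_gte(stats::median(rand_h) - stats::median(true_h), 100)
})
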