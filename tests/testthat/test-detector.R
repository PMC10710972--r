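test_that("circle offsets trace the radius-3 Bresenham circle clockwise", {
  off <- circle_offsets()
  expect_equal(nrow(off), 16L)
  expect_equal(off[1, ], c(dx = 0L, dy = -3L))
  expect_equal(off[2, ], c(dx = 1L, dy = -3L))  # clockwise with y down
  d <- sqrt(off[, 1]^2 + off[, 2]^2)
  expect_true(all(d >= 2.8 & d <= 3.2))
  expect_equal(nrow(unique(off)), 16L)
})

test_that("circle neighborhoods sample the right pixels and respect borders", {
  img <- flat_image(32, 32, 50)
  nb <- circle_neighborhood(img, 16, 16)
  expect_equal(nb$values, rep(50, 16))
  expect_equal(nb$center, 50)

  img2 <- matrix(0, 32, 32)
  img2[13, 16] <- 255  # directly above (16, 16) at distance 3
  nb2 <- circle_neighborhood(img2, 16, 16)
  expect_equal(nb2$values, c(255, rep(0, 15)))

  expect_error(circle_neighborhood(img, 3, 16), "border")
  expect_error(circle_neighborhood(img, 16, 30), "border")
})

test_that("adaptive threshold matches hand arithmetic", {
  # flat 100s: (1600 - 100 - 100) / 100 = 14
  expect_equal(adaptive_threshold(rep(100, 16), delta = 1, clamp = c(0, 255)), 14)
  # fifteen zeros and one 160: mean 10, (160 - 160 - 0)/10 = 0 -> clamp floor
  expect_equal(adaptive_threshold(c(rep(0, 15), 160), delta = 1, clamp = c(5, 80)), 5)
  # delta 0 collapses to the clamp floor
  expect_equal(adaptive_threshold(runif(16, 0, 255), delta = 0, clamp = c(5, 80)), 5)
  # all-black neighborhood is the degenerate case
  expect_equal(adaptive_threshold(rep(0, 16), delta = 1, clamp = c(5, 80)), 5)
})

test_that("adaptive threshold agrees with the brute-force oracle", {
  for (nb in random_neighborhoods(300, seed = 11)) {
    expect_equal(
      adaptive_threshold(nb, delta = 1.3, clamp = c(5, 80)),
      oracle_adaptive_threshold(nb, 1.3, 5, 80),
      tolerance = 1e-12
    )
  }
})

test_that("the adaptive threshold is invariant to intensity gain", {
  for (nb in random_neighborhoods(100, seed = 4)) {
    t0 <- adaptive_threshold(nb, delta = 1, clamp = c(0, 255))
    for (cc in c(0.25, 0.5, 2, 3.7)) {
      expect_equal(adaptive_threshold(cc * nb, delta = 1, clamp = c(0, 255)),
                   t0, tolerance = 1e-9)
    }
  }
})

test_that("segment test matches hand-scanned arcs", {
  # twelve contiguous +30 pixels at t = 20: response 12 * (30 - 20) = 120
  st <- segment_test(c(rep(130, 12), rep(100, 4)), t = 20, center = 100)
  expect_true(st$is_corner)
  expect_equal(st$response, 120)
  # flat neighborhood: no contrast, no corner
  st2 <- segment_test(rep(100, 16), t = 10, center = 100)
  expect_false(st2$is_corner)
  # eleven contiguous qualifying pixels are one too few
  st3 <- segment_test(c(rep(130, 11), rep(100, 5)), t = 20, center = 100)
  expect_false(st3$is_corner)
  # wrap-around contiguity: run split across the index seam
  st4 <- segment_test(c(rep(130, 6), rep(100, 4), rep(130, 6)), t = 20,
                      center = 100)
  expect_true(st4$is_corner)
  expect_equal(st4$response, 120)
})

test_that("segment test agrees with the brute-force oracle on random input", {
  withr::with_seed(21, {
    for (i in 1:300) {
      v <- runif(16, 0, 255)
      cen <- runif(1, 0, 255)
      t <- runif(1, 0, 60)
      got <- segment_test(v, t = t, center = cen)
      want <- oracle_segment_test(v, cen, t)
      expect_equal(got$is_corner, want$is_corner)
      expect_equal(got$response, want$response, tolerance = 1e-9)
    }
  })
})

test_that("detection is empty on constant images", {
  expect_equal(nrow(detect_keypoints(flat_image(64, 64),
                                     pipeline_config(pyramid_levels = 2))), 0L)
})

test_that("an isolated high-contrast spot yields exactly one keypoint", {
  img <- spot_image(48, 48, x0 = 24, y0 = 24)
  kps <- detect_keypoints(img, pipeline_config(pyramid_levels = 1))
  expect_equal(nrow(kps), 1L)
  expect_lte(abs(kps$x - 24), 1.5)
  expect_lte(abs(kps$y - 24), 1.5)
})

test_that("high-contrast detections survive a global gain change", {
  img <- spot_image(48, 48, bg = 50, fg = 250)
  half <- img / 2  # exact halving, no quantization loss
  k1 <- detect_keypoints(img, pipeline_config(pyramid_levels = 1))
  k2 <- detect_keypoints(half, pipeline_config(pyramid_levels = 1))
  expect_equal(nrow(k2), nrow(k1))
  expect_lte(max(abs(k1$x - k2$x)), 1)
  expect_lte(max(abs(k1$y - k2$y)), 1)
})

test_that("detect matches the exhaustive per-pixel oracle", {
  withr::with_seed(31, {
    for (i in 1:5) {
      img <- floor(matrix(runif(64 * 64, 0, 256), 64, 64))
      img[img > 255] <- 255
      kps <- detect_keypoints(img, pipeline_config(pyramid_levels = 1))
      ref <- oracle_detect_level(img, delta = 1.0, clamp = c(5, 80))
      expect_equal(nrow(kps), nrow(ref))
      expect_equal(kps$x, ref$x)
      expect_equal(kps$y, ref$y)
      expect_equal(kps$response, ref$response, tolerance = 1e-9)
      expect_equal(kps$threshold, ref$threshold, tolerance = 1e-9)
    }
  })
})

test_that("raising delta never increases the keypoint count", {
  img <- synth_image("texture", size = c(96, 96), seed = 3)
  counts <- vapply(c(0.5, 1, 1.5, 2, 3), function(d) {
    nrow(detect_keypoints(img, pipeline_config(delta = d, pyramid_levels = 2)))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("output is deterministically ordered by level, y, x", {
  img <- synth_image("texture", size = c(96, 96), seed = 6)
  kps <- detect_keypoints(img, pipeline_config(pyramid_levels = 3))
  expect_false(is.unsorted(order(kps$level, kps$y, kps$x)))
  expect_identical(kps, detect_keypoints(img, pipeline_config(pyramid_levels = 3)))
})

test_that("the adaptive detector reaches the dark half that fixed t=20 misses", {
  endo <- synth_image("endoscopy", seed = 3)
  ka <- detect_keypoints(endo)
  kf <- detect_keypoints(endo, pipeline_config(threshold_mode = "fixed",
                                               fixed_threshold = 20))
  med <- stats::median(endo)
  at_px <- function(k) {
    endo[cbind(pmin(pmax(round(k$base_y), 1), nrow(endo)),
               pmin(pmax(round(k$base_x), 1), ncol(endo)))]
  }
  expect_gt(sum(at_px(ka) < med), 0)     # adaptive sees the dark half
  expect_gt(sum(at_px(ka) >= med), 0)    # and the bright half
  expect_equal(sum(at_px(kf) < med), 0)  # fixed t=20 sees none in the dark
})

test_that("the contrast-mode variant runs and differs from the literal rule", {
  nb <- c(rep(50, 15), 100)
  t_lit <- adaptive_threshold(nb, delta = 1, clamp = c(0, 255))
  t_con <- adaptive_threshold(list(values = nb, center = 90), delta = 1,
                              clamp = c(0, 255), contrast = TRUE)
  expect_false(isTRUE(all.equal(t_lit, t_con)))
  img <- synth_image("texture", size = c(64, 64), seed = 9)
  cfg <- pipeline_config(pyramid_levels = 1, contrast_mode = TRUE)
  expect_s3_class(detect_keypoints(img, cfg), "tbl_df")
})
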