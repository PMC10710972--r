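#' Matching score
#'
#' The repeatability fraction `MS = CM / N` with `N = min(n1, n2)`:
#' verified ("correct") matches over the smaller of the two images'
#' keypoint counts, reported to three decimals.
#'
#' @param cm Number of correct (verified) matches.
#' @param n1,n2 Keypoint counts of the two images (each >= 1).
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' matching_score(280, 377, 420) # 0.743
matching_score <- function(cm, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (cm < 0 || cm > min(n1, n2)) {
    stop("cm must lie in [0, min(n1, n2)]")
  }
  round(cm / min(n1, n2), 3)
}

#' Angular error of an estimated homography against a known rotation
#'
#' Extracts the rotation angle of the homography's upper-left 2x2 block
#' by polar decomposition (the nearest rotation matrix in the Frobenius
#' sense) and returns the absolute difference to the true angle, wrapped
#' into `[0, pi]`.
#'
#' @param H_est Estimated 3x3 homography (invertible).
#' @param theta_true True rotation angle in radians.
#' @return Absolute angular error in radians.
#' @export
rotation_error <- function(H_est, theta_true) {
  stopifnot(is.matrix(H_est), all(dim(H_est) == c(3, 3)))
  d <- det(H_est)
  if (!is.finite(d) || abs(d) < 1e-12) stop("homography is not invertible")
  A <- H_est[1:2, 1:2]
  s <- svd(A)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { # reflection: flip the smallest singular direction
    s$v[, 2] <- -s$v[, 2]
    R <- s$u %*% t(s$v)
  }
  ang <- atan2(R[2, 1], R[1, 1])
  err <- abs(ang - theta_true)
  err <- err %% (2 * pi)
  if (err > pi) err <- 2 * pi - err
  err
}

#' Rotation-sweep evaluation
#'
#' For each angle: rotate the image about its center (bilinear, borders
#' filled with the image mean, ground-truth homography recorded), run the
#' full matching pipeline between original and rotated frame, and report
#' the verified match count `CM`, the matching score `MS = CM / min(n1,
#' n2)` and the angular error of the recovered homography. A failed angle
#' yields a `CM = 0` record with a warning rather than aborting the
#' sweep.
#'
#' @param img Grayscale matrix.
#' @param angles Rotation angles in degrees (default 5..30 by 5).
#' @param config A [pipeline_config()].
#' @param selection Optional descriptor pair selection.
#' @return Tibble with `angle, error, correct_features, matching_score,
#'   n1, n2` (`error` in radians).
#' @export
run_rotation_experiment <- function(img, angles = seq(5, 30, by = 5),
                                    config = pipeline_config(),
                                    selection = NULL) {
  stopifnot(length(angles) >= 1L)
  recs <- lapply(angles, function(a) {
    H_true <- rotation_homography(a, dim(img))
    rot <- warp_image(img, H_true)
    res <- tryCatch(
      match_images(img, rot$image, config, selection),
      warning = function(w) {
        warning("angle ", a, ": ", conditionMessage(w), call. = FALSE)
        suppressWarnings(match_images(img, rot$image, config, selection))
      },
      error = function(e) {
        warning("angle ", a, " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    summarize_record(res, label = a, theta_true = a * pi / 180)
  })
  out <- dplyr::bind_rows(recs)
  names(out)[names(out) == "label"] <- "angle"
  out
}

#' Consecutive-frame tracking evaluation
#'
#' Matches the first frame against every subsequent frame and reports the
#' verified match count and matching score per frame, quantifying how
#' stably features can be tracked as the view drifts.
#'
#' @param frames Ordered list of grayscale matrices (>= 2).
#' @param config A [pipeline_config()].
#' @param selection Optional descriptor pair selection.
#' @return Tibble with `frame, correct_features, matching_score, n1, n2`
#'   (one row per frame 2..K).
#' @export
run_sequence_experiment <- function(frames, config = pipeline_config(),
                                    selection = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("need an ordered list of at least 2 frames")
  }
  recs <- lapply(2:length(frames), function(k) {
    res <- tryCatch(
      suppressWarnings(match_images(frames[[1]], frames[[k]], config, selection)),
      error = function(e) {
        warning("frame ", k, " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    summarize_record(res, label = k, theta_true = NULL)
  })
  out <- dplyr::bind_rows(recs)
  names(out)[names(out) == "label"] <- "frame"
  out
}

summarize_record <- function(res, label, theta_true = NULL) {
  if (is.null(res)) {
    rec <- tibble(label = label, correct_features = 0L,
                  matching_score = NA_real_, n1 = 0L, n2 = 0L)
    if (!is.null(theta_true)) rec <- tibble::add_column(rec, error = NA_real_,
                                                        .after = "label")
    return(rec)
  }
  n1 <- nrow(res$keypoints_a); n2 <- nrow(res$keypoints_b)
  cm <- sum(res$matches$passed_ransac %in% TRUE)
  ms <- if (min(n1, n2) >= 1) matching_score(min(cm, n1, n2), n1, n2) else NA_real_
  rec <- tibble(label = label, correct_features = cm,
                matching_score = ms, n1 = n1, n2 = n2)
  if (!is.null(theta_true)) {
    err <- if (is.null(res$homography)) {
      NA_real_
    } else {
      rotation_error(res$homography, theta_true)
    }
    rec <- tibble::add_column(rec, error = err, .after = "label")
  }
  rec
}

#' Adaptive versus fixed-threshold ablation
#'
#' Runs the identical describe/match/verify pipeline twice on the same
#' image pair -- once with the per-pixel adaptive threshold, once with
#' classical fixed-threshold FAST -- and reports verified matches and
#' matching score per condition. On unevenly illuminated frames the
#' adaptive detector reaches features in the dark periphery that a fixed
#' threshold misses.
#'
#' @param img_a,img_b Grayscale matrices.
#' @param config A [pipeline_config()] (its `threshold_mode` is
#'   overridden per condition).
#' @param fixed_t Threshold of the fixed condition (default 20).
#' @param selection Optional descriptor pair selection.
#' @return Tibble with `method, correct_features, matching_score, n1, n2`.
#' @export
compare_adaptive_vs_fixed <- function(img_a, img_b,
                                      config = pipeline_config(),
                                      fixed_t = 20, selection = NULL) {
  run_one <- function(mode) {
    cfg <- config
    cfg$threshold_mode <- mode
    cfg$fixed_threshold <- fixed_t
    res <- tryCatch(
      suppressWarnings(match_images(img_a, img_b, cfg, selection)),
      error = function(e) NULL
    )
    rec <- summarize_record(res, label = mode)
    names(rec)[names(rec) == "label"] <- "method"
    rec
  }
  dplyr::bind_rows(run_one("adaptive"), run_one("fixed"))
}
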