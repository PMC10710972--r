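#' Plot a grayscale image
#'
#' @param img Grayscale matrix.
#' @return A ggplot object (raster, y axis pointing down as in image
#'   coordinates).
#' @export
plot_image <- function(img) {
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Overlay detected keypoints on their image
#'
#' @param img Grayscale matrix the keypoints were detected on.
#' @param kps Keypoint tibble from [detect_keypoints()] (base coordinates
#'   are used).
#' @return A ggplot object.
#' @export
plot_keypoints <- function(img, kps) {
  plot_image(img) +
    ggplot2::geom_point(
      data = kps,
      ggplot2::aes(.data$base_x, .data$base_y, color = factor(.data$level)),
      inherit.aes = FALSE, size = 0.8, alpha = 0.8
    ) +
    ggplot2::labs(color = "level") +
    ggplot2::theme(legend.position = "right")
}

#' Visualize verified matches between two images
#'
#' Draws the two images side by side and connects verified
#' correspondences.
#'
#' @param res A `capfeat_match` from [match_images()].
#' @param img_a,img_b The two matched images.
#' @param stage Which surviving stage to draw: `"ransac"` (default),
#'   `"gms"` or `"coarse"`.
#' @return A ggplot object.
#' @export
plot_matches <- function(res, img_a, img_b, stage = c("ransac", "gms", "coarse")) {
  stage <- match.arg(stage)
  keep <- switch(stage,
    ransac = res$matches$passed_ransac %in% TRUE,
    gms = res$matches$passed_gms %in% TRUE,
    coarse = rep(TRUE, nrow(res$matches))
  )
  m <- res$matches[keep, ]
  off <- ncol(img_a) + 10
  seg <- tibble(
    x = res$keypoints_a$base_x[m$index_a],
    y = res$keypoints_a$base_y[m$index_a],
    xend = res$keypoints_b$base_x[m$index_b] + off,
    yend = res$keypoints_b$base_y[m$index_b]
  )
  big <- matrix(255, max(nrow(img_a), nrow(img_b)), off + ncol(img_b))
  big[seq_len(nrow(img_a)), seq_len(ncol(img_a))] <- img_a
  big[seq_len(nrow(img_b)), off + seq_len(ncol(img_b))] <- img_b
  plot_image(big) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, color = "cyan", linewidth = 0.2, alpha = 0.6
    )
}

#' Plot an evaluation record table
#'
#' Line plots of correct features and matching score against the sweep
#' label (rotation angle or frame index).
#'
#' @param records Tibble from [run_rotation_experiment()] or
#'   [run_sequence_experiment()].
#' @return A ggplot object.
#' @export
plot_evaluation <- function(records) {
  xcol <- if ("angle" %in% names(records)) "angle" else "frame"
  long <- dplyr::bind_rows(
    tibble(x = records[[xcol]], value = records$correct_features,
           metric = "correct features"),
    tibble(x = records[[xcol]], value = records$matching_score,
           metric = "matching score")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = xcol, y = NULL)
}
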