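#' Pipeline configuration
#'
#' Collects every tuning knob of the detection/description/matching
#' pipeline in one validated list. Defaults follow the method's stated
#' design: an 8-level pyramid with scale factor 1.5, a 12-of-16 FAST
#' segment test, a 512-bit descriptor, GMS with a 20x20 grid, and RANSAC
#' at a 3 px reprojection tolerance.
#'
#' @param delta Global scale of the adaptive threshold (dimensionless).
#'   The per-pixel threshold is `delta * (sum(I) - max(I) - min(I)) / mean(I)`
#'   over the 16 circle intensities; on a flat neighborhood this equals
#'   `14 * delta`, so the default 1.0 yields t = 14 there -- within the
#'   conventional FAST threshold range while leaving headroom below the
#'   classical fixed t = 20 for the low-contrast features that uneven
#'   illumination produces.
#' @param pyramid_levels Number of pyramid levels (>= 1).
#' @param pyramid_factor Downsampling ratio between consecutive levels (> 1).
#' @param pyramid_sigma Gaussian blur scale applied before each downsample.
#' @param fast_arc_length Required number of contiguous qualifying circle
#'   pixels (12 of 16).
#' @param threshold_clamp Length-2 numeric `(min, max)`: the adaptive
#'   threshold is clipped into this intensity range. The floor keeps the
#'   detector from firing on noise in near-flat regions.
#' @param nms_enabled Apply 3x3 non-maximum suppression on the FAST
#'   response within each level.
#' @param descriptor_bits Final descriptor length (0 < bits <= 903).
#' @param pattern_scale Radius of the outermost descriptor sampling circle,
#'   in pixels of the keypoint's own pyramid level.
#' @param gms_grid Grid cells per image side for motion-statistics filtering.
#' @param gms_alpha Support threshold factor: a match is kept when its
#'   neighborhood support exceeds `gms_alpha * sqrt(n)` matches.
#' @param ransac_reproj_px Symmetric reprojection error tolerance (pixels).
#' @param ransac_conf Target confidence for the adaptive iteration count.
#' @param ransac_max_iter Iteration cap.
#' @param rng_seed Seed for every stochastic stage (RANSAC sampling).
#' @param threshold_mode `"adaptive"` (per-pixel rule) or `"fixed"`
#'   (classical FAST with `fixed_threshold` everywhere) -- the fixed mode
#'   exists for ablation comparisons.
#' @param fixed_threshold Threshold used when `threshold_mode = "fixed"`.
#' @param contrast_mode If `TRUE`, the adaptive rule is evaluated on the
#'   center contrasts `|I_i - I_c|` instead of the raw circle intensities.
#'   Off by default; see the methods vignette.
#'
#' @return A validated list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(delta = 1.2, pyramid_levels = 4)
#' cfg$delta
pipeline_config <- function(delta = 1.0,
                            pyramid_levels = 8L,
                            pyramid_factor = 1.5,
                            pyramid_sigma = 1.0,
                            fast_arc_length = 12L,
                            threshold_clamp = c(5, 80),
                            nms_enabled = TRUE,
                            descriptor_bits = 512L,
                            pattern_scale = 15,
                            gms_grid = 20L,
                            gms_alpha = 0.75,
                            ransac_reproj_px = 3,
                            ransac_conf = 0.995,
                            ransac_max_iter = 2000L,
                            rng_seed = 1L,
                            threshold_mode = c("adaptive", "fixed"),
                            fixed_threshold = 20,
                            contrast_mode = FALSE) {
  cfg <- list(
    delta = as.numeric(delta),
    pyramid_levels = as.integer(pyramid_levels),
    pyramid_factor = as.numeric(pyramid_factor),
    pyramid_sigma = as.numeric(pyramid_sigma),
    fast_arc_length = as.integer(fast_arc_length),
    threshold_clamp = as.numeric(threshold_clamp),
    nms_enabled = isTRUE(nms_enabled),
    descriptor_bits = as.integer(descriptor_bits),
    pattern_scale = as.numeric(pattern_scale),
    gms_grid = as.integer(gms_grid),
    gms_alpha = as.numeric(gms_alpha),
    ransac_reproj_px = as.numeric(ransac_reproj_px),
    ransac_conf = as.numeric(ransac_conf),
    ransac_max_iter = as.integer(ransac_max_iter),
    rng_seed = as.integer(rng_seed),
    threshold_mode = match.arg(threshold_mode),
    fixed_threshold = as.numeric(fixed_threshold),
    contrast_mode = isTRUE(contrast_mode)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    "delta must be >= 0" = cfg$delta >= 0,
    "pyramid_levels must be >= 1" = cfg$pyramid_levels >= 1L,
    "pyramid_factor must be > 1" = cfg$pyramid_factor > 1,
    "fast_arc_length must be in 1..16" =
      cfg$fast_arc_length >= 1L && cfg$fast_arc_length <= 16L,
    "descriptor_bits must be in 1..903" =
      cfg$descriptor_bits >= 1L && cfg$descriptor_bits <= 903L,
    "threshold_clamp must be length 2" = length(cfg$threshold_clamp) == 2L,
    "threshold_clamp must satisfy 0 <= min <= max <= 255" =
      cfg$threshold_clamp[1] >= 0 &&
        cfg$threshold_clamp[1] <= cfg$threshold_clamp[2] &&
        cfg$threshold_clamp[2] <= 255,
    "ransac_conf must be in (0, 1)" =
      cfg$ransac_conf > 0 && cfg$ransac_conf < 1,
    "threshold_mode must be adaptive or fixed" =
      cfg$threshold_mode %in% c("adaptive", "fixed")
  )
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

# Serialization: flat key=value lines, one per field; threshold_clamp is
# written as "min,max". Unknown keys on read are an error (fail loud).

#' Write / read a pipeline configuration file
#'
#' Flat `key=value` text format; every field of [pipeline_config()]
#' round-trips unchanged. Unknown keys in a file are an error.
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fmt <- function(v) {
    if (is.logical(v)) {
      if (v) "true" else "false"
    } else if (is.character(v)) {
      v
    } else {
      paste(vapply(v, function(x) format(x, digits = 17), ""), collapse = ",")
    }
  }
  lines <- vapply(names(cfg), function(k) paste0(k, "=", fmt(cfg[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  defaults <- pipeline_config()
  cfg <- unclass(defaults)
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(p[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    old <- cfg[[key]]
    cfg[[key]] <- if (is.logical(old)) {
      identical(tolower(val), "true")
    } else if (is.character(old)) {
      val
    } else if (is.integer(old)) {
      as.integer(val)
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  cfg <- structure(cfg, class = "pipeline_config")
  validate_config(cfg)
  cfg
}
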