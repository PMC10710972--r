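#' Read an image as an 8-bit grayscale matrix
#'
#' Supports PNG, JPEG and PGM (binary P5 or ASCII P2, maxval <= 255).
#' Color inputs are converted to luma with BT.601 weights
#' (0.299, 0.587, 0.114) and rounded half-up, matching how 8-bit pipelines
#' conventionally grayscale RGB frames.
#'
#' @param path Path to a PNG/JPEG/PGM file.
#' @return Numeric matrix `img[h, w]` with integer intensities in `[0, 255]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    gray_from_array(arr)
  } else if (ext %in% c("jpg", "jpeg")) {
    arr <- jpeg::readJPEG(path)
    gray_from_array(arr)
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported image format: .", ext, " (expected png, jpeg or pgm)")
  }
}

# readPNG/readJPEG return values in [0,1]; scale to 0-255 before luma so
# rounding happens on the 8-bit scale.
gray_from_array <- function(arr) {
  if (length(dim(arr)) == 2L) {
    g <- arr * 255
  } else {
    nc <- dim(arr)[3]
    if (nc == 1L) {
      g <- arr[, , 1] * 255
    } else {
      # BT.601 luma; channel 4 (alpha) ignored
      g <- 0.299 * arr[, , 1] * 255 + 0.587 * arr[, , 2] * 255 +
        0.114 * arr[, , 3] * 255
    }
  }
  round_half_up(g)
}

round_half_up <- function(x) floor(x + 0.5)

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval; '#' comments allowed
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval)) stop("malformed PGM header")
  if (maxval > 255L) stop("PGM maxval > 255 not supported")
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
    if (length(vals) < w * h) stop("truncated PGM pixel data")
  } else if (magic == "P2") {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    if (length(vals) < w * h || anyNA(vals)) stop("malformed PGM pixel data")
    vals <- vals[seq_len(w * h)]
  } else {
    stop("unsupported PGM magic: ", magic)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale matrix to disk
#'
#' Format chosen by extension: `.png` (via the png package) or `.pgm`
#' (binary P5). Intensities are clipped to `[0, 255]` and rounded.
#'
#' @param img Numeric matrix with values in `[0, 255]`.
#' @param path Output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  stopifnot(is.matrix(img))
  v <- round_half_up(pmin(pmax(img, 0), 255))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(v), nrow(v)), con, eos = NULL)
    writeBin(as.raw(as.integer(t(v))), con)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Keypoint / descriptor / match / homography serialization. All artifacts are
# plain text and round-trip through their reader/writer.

#' Write / read keypoints as TSV
#'
#' Columns `x, y, level, response, angle_rad, threshold`, written to six
#' decimals; `read_keypoints(write_keypoints(k))` reproduces `k` to that
#' precision. Coordinates are level-local, 1-based pixel centers; `level`
#' is the 0-based pyramid index.
#'
#' @param kps Keypoint tibble (as returned by [detect_keypoints()]).
#' @param path File path.
#' @return `read_keypoints()` returns a keypoint tibble; `write_keypoints()`
#'   returns `path` invisibly.
#' @export
write_keypoints <- function(kps, path) {
  hdr <- "x\ty\tlevel\tresponse\tangle_rad\tthreshold"
  ang <- if ("angle" %in% names(kps)) kps$angle else rep(NA_real_, nrow(kps))
  ang[is.na(ang)] <- 0
  rows <- sprintf("%.6f\t%.6f\t%d\t%.6f\t%.6f\t%.6f",
                  kps$x, kps$y, as.integer(kps$level), kps$response,
                  ang, kps$threshold)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_keypoints
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop("keypoint file not found: ", path)
  lines <- readLines(path)
  expected <- "x\ty\tlevel\tresponse\tangle_rad\tthreshold"
  if (length(lines) == 0L || lines[1] != expected) {
    stop("bad keypoint header in ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parse_row <- function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L) stop("line ", i + 1L, ": expected 6 fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("line ", i + 1L, ": non-numeric field in keypoint file")
    v
  }
  if (length(body) == 0L) {
    return(tibble(
      x = numeric(0), y = numeric(0), level = integer(0),
      response = numeric(0), angle = numeric(0), threshold = numeric(0)
    ))
  }
  m <- t(vapply(seq_along(body), parse_row, numeric(6)))
  tibble(
    x = m[, 1], y = m[, 2], level = as.integer(m[, 3]),
    response = m[, 4], angle = m[, 5], threshold = m[, 6]
  )
}

#' Write / read binary descriptors as hex strings
#'
#' One row per keypoint: a hex string of the packed bit vector, first
#' descriptor bit in the most significant position of the first hex digit.
#' A 512-bit descriptor is 128 hex characters.
#'
#' @param bits Integer 0/1 matrix, one descriptor per row.
#' @param path File path.
#' @return `read_descriptors()` returns the 0/1 integer matrix;
#'   `write_descriptors()` returns `path` invisibly.
#' @export
write_descriptors <- function(bits, path) {
  stopifnot(is.matrix(bits))
  writeLines(apply(bits, 1, bits_to_hex), path)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  if (!file.exists(path)) stop("descriptor file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  rows <- lapply(seq_along(lines), function(i) {
    b <- hex_to_bits(lines[i])
    if (is.null(b)) stop("line ", i, ": invalid hex descriptor")
    b
  })
  nb <- unique(lengths(rows))
  if (length(nb) != 1L) stop("descriptor rows have differing lengths")
  do.call(rbind, rows)
}

bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (4 - n %% 4) %% 4
  b <- c(as.integer(bits), rep(0L, pad))
  q <- matrix(b, nrow = 4)
  vals <- q[1, ] * 8L + q[2, ] * 4L + q[3, ] * 2L + q[4, ]
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_bits <- function(s) {
  ch <- strsplit(tolower(s), "")[[1]]
  vals <- match(ch, c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                      "a", "b", "c", "d", "e", "f")) - 1L
  if (anyNA(vals)) return(NULL)
  as.integer(rbind(vals %/% 8L, (vals %/% 4L) %% 2L, (vals %/% 2L) %% 2L, vals %% 2L))
}

#' Write / read a match table as TSV
#'
#' Columns `index_a, index_b, hamming, passed_gms, passed_ransac`.
#'
#' @param matches Match tibble.
#' @param path File path.
#' @return `read_matches()` returns the match tibble; `write_matches()`
#'   returns `path` invisibly.
#' @export
write_matches <- function(matches, path) {
  hdr <- "index_a\tindex_b\thamming\tpassed_gms\tpassed_ransac"
  flag <- function(v) ifelse(is.na(v), "NA", ifelse(v, "1", "0"))
  rows <- sprintf("%d\t%d\t%d\t%s\t%s",
                  as.integer(matches$index_a), as.integer(matches$index_b),
                  as.integer(matches$hamming),
                  flag(matches$passed_gms), flag(matches$passed_ransac))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  if (!file.exists(path)) stop("match file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L ||
      lines[1] != "index_a\tindex_b\thamming\tpassed_gms\tpassed_ransac") {
    stop("bad match header in ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(tibble(
      index_a = integer(0), index_b = integer(0), hamming = integer(0),
      passed_gms = logical(0), passed_ransac = logical(0)
    ))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 5L)
  if (length(bad)) stop("line ", bad[1] + 1L, ": expected 5 fields")
  m <- do.call(rbind, f)
  parse_flag <- function(v) ifelse(v == "NA", NA, v == "1")
  tibble(
    index_a = as.integer(m[, 1]), index_b = as.integer(m[, 2]),
    hamming = as.integer(m[, 3]),
    passed_gms = parse_flag(m[, 4]), passed_ransac = parse_flag(m[, 5])
  )
}

#' Write / read a homography
#'
#' Nine whitespace-separated numbers, row-major, full precision.
#'
#' @param H 3x3 numeric matrix.
#' @param path File path.
#' @return `read_homography()` returns the 3x3 matrix; `write_homography()`
#'   returns `path` invisibly.
#' @export
write_homography <- function(H, path) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  writeLines(paste(vapply(as.vector(t(H)), function(x) format(x, digits = 17), ""),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  if (!file.exists(path)) stop("homography file not found: ", path)
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != 9L) stop("homography file must contain 9 numbers")
  matrix(v, nrow = 3, byrow = TRUE)
}
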