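// Compiled kernels for the per-pixel stages of the pipeline.
//
// Conventions shared with the R side:
//  * an image is a numeric matrix img[h, w] holding intensities in [0, 255];
//    row index = y (down), column index = x (right);
//  * user-facing coordinates are 1-based with pixel centers at integer
//    positions, i.e. (x = 1, y = 1) is the center of the top-left pixel;
//  * angles are in radians; a rotation by `a` maps an offset (dx, dy) to
//    (dx cos a - dy sin a, dx sin a + dy cos a) in the image frame.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gaussian blur, separable, kernel truncated at 3*sigma, symmetric reflection
// at the borders ( c b a | a b c ).

static int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cf_gaussian_blur(NumericMatrix img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(h, w), out(h, w);
  // horizontal pass
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(y, reflect_idx(x + i, w));
      tmp(y, x) = acc;
    }
  // vertical pass
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(reflect_idx(y + i, h), x);
      out(y, x) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Bilinear resize with center-aligned sampling; constants are preserved.

// [[Rcpp::export]]
NumericMatrix cf_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sy = (double)h / out_h, sx = (double)w / out_w;
  for (int y = 0; y < out_h; ++y) {
    double fy = (y + 0.5) * sy - 0.5;
    int y0 = (int)std::floor(fy);
    double wy = fy - y0;
    int y0c = std::min(std::max(y0, 0), h - 1);
    int y1c = std::min(std::max(y0 + 1, 0), h - 1);
    for (int x = 0; x < out_w; ++x) {
      double fx = (x + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(fx);
      double wx = fx - x0;
      int x0c = std::min(std::max(x0, 0), w - 1);
      int x1c = std::min(std::max(x0 + 1, 0), w - 1);
      out(y, x) = (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
                  wy * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Inverse bilinear warp: out(x, y) = img(Hinv %*% (x, y, 1)), 1-based coords,
// out-of-image samples take `fill`.

// [[Rcpp::export]]
NumericMatrix cf_warp(NumericMatrix img, NumericMatrix Hinv, double fill,
                      int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  for (int y = 1; y <= out_h; ++y) {
    for (int x = 1; x <= out_w; ++x) {
      double X = Hinv(0, 0) * x + Hinv(0, 1) * y + Hinv(0, 2);
      double Y = Hinv(1, 0) * x + Hinv(1, 1) * y + Hinv(1, 2);
      double Z = Hinv(2, 0) * x + Hinv(2, 1) * y + Hinv(2, 2);
      double sx = X / Z, sy = Y / Z;
      double v;
      if (sx < 1.0 || sx > (double)w || sy < 1.0 || sy > (double)h) {
        v = fill;
      } else {
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        double wx = sx - x0, wy = sy - y0;
        int x1 = std::min(x0 + 1, w), y1 = std::min(y0 + 1, h);
        v = (1 - wy) * ((1 - wx) * img(y0 - 1, x0 - 1) + wx * img(y0 - 1, x1 - 1)) +
            wy * ((1 - wx) * img(y1 - 1, x0 - 1) + wx * img(y1 - 1, x1 - 1));
      }
      out(y - 1, x - 1) = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// FAST segment test with the per-pixel adaptive threshold.
//
// Circle offsets: radius-3 Bresenham circle, 16 points, clockwise starting at
// 12 o'clock, i.e. (0,-3) first (dx, dy with y down).
static const int CIRC_DX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int CIRC_DY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

// [[Rcpp::export]]
IntegerMatrix cf_circle_offsets() {
  IntegerMatrix m(16, 2);
  for (int i = 0; i < 16; ++i) { m(i, 0) = CIRC_DX[i]; m(i, 1) = CIRC_DY[i]; }
  return m;
}

// Adaptive threshold of one neighborhood: t = delta * (sum - max - min) / mean,
// clamped; all-zero (or degenerate) neighborhoods fall back to the clamp floor.
static double adaptive_t(const double* v, double delta, double cmin, double cmax) {
  double sum = 0.0, mx = v[0], mn = v[0];
  for (int i = 0; i < 16; ++i) {
    sum += v[i];
    if (v[i] > mx) mx = v[i];
    if (v[i] < mn) mn = v[i];
  }
  if (sum <= 0.0) return cmin;
  double mean = sum / 16.0;
  double t = delta * (sum - mx - mn) / mean;
  if (t < cmin) t = cmin;
  if (t > cmax) t = cmax;
  return t;
}

// Segment test: corner iff >= arc_len circularly contiguous circle pixels all
// brighter than center + t or all darker than center - t.  Response = the
// largest, over maximal qualifying runs, of sum(|I_i - c| - t) along the run.
static bool segment_test_core(const double* v, double c, double t, int arc_len,
                              double* response) {
  double best = 0.0;
  bool corner = false;
  for (int side = 0; side < 2; ++side) {
    bool q[32];
    for (int i = 0; i < 32; ++i) {
      double d = v[i % 16] - c;
      q[i] = side == 0 ? (d > t) : (-d > t);
    }
    // full-circle run
    bool all = true;
    for (int i = 0; i < 16; ++i) all = all && q[i];
    if (all) {
      double s = 0.0;
      for (int i = 0; i < 16; ++i) s += std::fabs(v[i] - c) - t;
      corner = true;
      if (s > best) best = s;
      continue;
    }
    // maximal runs over the doubled array; runs starting at i with !q[i-1]
    for (int i = 0; i < 16; ++i) {
      if (q[i] && !q[(i + 15) % 16]) {
        int len = 0;
        double s = 0.0;
        int j = i;
        while (len < 16 && q[j % 16]) {
          s += std::fabs(v[j % 16] - c) - t;
          ++len;
          ++j;
        }
        if (len >= arc_len) {
          corner = true;
          if (s > best) best = s;
        }
      }
    }
  }
  *response = best;
  return corner;
}

// [[Rcpp::export]]
List cf_segment_test(NumericVector values, double center, double t, int arc_len) {
  double v[16];
  for (int i = 0; i < 16; ++i) v[i] = values[i];
  double resp = 0.0;
  bool corner = segment_test_core(v, center, t, arc_len, &resp);
  return List::create(_["is_corner"] = corner, _["response"] = resp);
}

// Full-frame detection on one pyramid level.  Modes:
//   fixed_mode  - use fixed_t everywhere instead of the adaptive rule;
//   contrast_mode - evaluate the adaptive rule on |I_i - I_c| instead of I_i.
// Returns an n x 4 matrix: x, y (1-based), response, threshold, ordered by
// y then x.
// [[Rcpp::export]]
NumericMatrix cf_detect_level(NumericMatrix img, double delta, double cmin,
                              double cmax, int arc_len, bool contrast_mode,
                              bool fixed_mode, double fixed_t, bool nms) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix resp(h, w), thr(h, w);
  std::fill(resp.begin(), resp.end(), 0.0);

  double v[16], a[16];
  for (int y = 3; y < h - 3; ++y) {
    for (int x = 3; x < w - 3; ++x) {
      double c = img(y, x);
      for (int i = 0; i < 16; ++i) v[i] = img(y + CIRC_DY[i], x + CIRC_DX[i]);
      double t;
      if (fixed_mode) {
        t = fixed_t;
      } else if (contrast_mode) {
        for (int i = 0; i < 16; ++i) a[i] = std::fabs(v[i] - c);
        t = adaptive_t(a, delta, cmin, cmax);
      } else {
        t = adaptive_t(v, delta, cmin, cmax);
      }
      thr(y, x) = t;
      double r = 0.0;
      if (segment_test_core(v, c, t, arc_len, &r)) resp(y, x) = r;
    }
  }

  std::vector<double> xs, ys, rs, ts;
  for (int y = 3; y < h - 3; ++y) {
    for (int x = 3; x < w - 3; ++x) {
      double r = resp(y, x);
      if (r <= 0.0) continue;
      if (nms) {
        // 3x3 non-maximum suppression; on plateaus the pixel latest in
        // reading order survives (strict > against later neighbors,
        // >= against earlier ones)
        bool keep = true;
        for (int dy = -1; dy <= 1 && keep; ++dy)
          for (int dx = -1; dx <= 1 && keep; ++dx) {
            if (dx == 0 && dy == 0) continue;
            double nr = resp(y + dy, x + dx);
            bool later = (dy > 0) || (dy == 0 && dx > 0);
            if (later ? (r <= nr) : (r < nr)) keep = false;
          }
        if (!keep) continue;
      }
      xs.push_back(x + 1.0);
      ys.push_back(y + 1.0);
      rs.push_back(r);
      ts.push_back(thr(y, x));
    }
  }
  int n = xs.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = rs[i]; out(i, 3) = ts[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// FREAK-style retinal sampling.

// Gaussian-weighted mean intensity of a receptive field centered at the
// (real-valued) position (cx + rdx, cy + rdy), window truncated at 3*sigma.
static bool receptive_sample(NumericMatrix& img, double px, double py,
                             double sigma, double* out) {
  int h = img.nrow(), w = img.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  int x0 = (int)std::floor(px) - r, x1 = (int)std::ceil(px) + r;
  int y0 = (int)std::floor(py) - r, y1 = (int)std::ceil(py) + r;
  if (x0 < 1 || y0 < 1 || x1 > w || y1 > h) return false;
  double acc = 0.0, wsum = 0.0, s2 = 2.0 * sigma * sigma;
  for (int y = y0; y <= y1; ++y) {
    double dy = y - py;
    for (int x = x0; x <= x1; ++x) {
      double dx = x - px;
      double g = std::exp(-(dx * dx + dy * dy) / s2);
      acc += g * img(y - 1, x - 1);
      wsum += g;
    }
  }
  *out = acc / wsum;
  return true;
}

// [[Rcpp::export]]
NumericVector cf_smoothed_sample(NumericMatrix img, double cx, double cy,
                                 double dx, double dy, double sigma,
                                 double angle) {
  double ca = std::cos(angle), sa = std::sin(angle);
  double px = cx + dx * ca - dy * sa;
  double py = cy + dx * sa + dy * ca;
  double v = NA_REAL;
  if (!receptive_sample(img, px, py, sigma, &v)) return NumericVector::create(NA_REAL);
  return NumericVector::create(v);
}

// Sample all pattern points at a given orientation; returns false if any
// receptive field window leaves the image.
static bool sample_pattern(NumericMatrix& img, double cx, double cy,
                           NumericMatrix& pts, double angle,
                           std::vector<double>& vals) {
  int np = pts.nrow();
  double ca = std::cos(angle), sa = std::sin(angle);
  for (int i = 0; i < np; ++i) {
    double dx = pts(i, 0), dy = pts(i, 1), sg = pts(i, 2);
    double px = cx + dx * ca - dy * sa;
    double py = cy + dx * sa + dy * ca;
    if (!receptive_sample(img, px, py, sg, &vals[i])) return false;
  }
  return true;
}

// Orientation: accumulate (I_i - I_j) * (o_i - o_j)/||o_i - o_j|| over the
// diametrically opposed same-circle pairs, take atan2 of the summed vector.
static double pattern_orientation(const std::vector<double>& vals,
                                  NumericMatrix& pts, IntegerMatrix& opairs) {
  double gx = 0.0, gy = 0.0;
  for (int k = 0; k < opairs.nrow(); ++k) {
    int i = opairs(k, 0), j = opairs(k, 1);
    double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1);
    double nrm = std::sqrt(dx * dx + dy * dy);
    if (nrm <= 0) continue;
    double d = vals[i] - vals[j];
    gx += d * dx / nrm;
    gy += d * dy / nrm;
  }
  if (gx == 0.0 && gy == 0.0) return 0.0;
  return std::atan2(gy, gx);
}

// Describe a batch of keypoints on one image.  kxy: n x 2 (1-based x, y).
// Returns keep flags, orientation angles and the raw 903-bit matrix.
// forced_angle: if non-empty, skip orientation estimation and use these.
// [[Rcpp::export]]
List cf_freak_batch(NumericMatrix img, NumericMatrix kxy, NumericMatrix pts,
                    IntegerMatrix pairs, IntegerMatrix opairs,
                    NumericVector forced_angle) {
  int n = kxy.nrow(), np = pts.nrow(), nb = pairs.nrow();
  LogicalVector keep(n);
  NumericVector angle(n);
  IntegerMatrix bits(n, nb);
  std::vector<double> vals(np);
  bool forced = forced_angle.size() == n;

  for (int k = 0; k < n; ++k) {
    double cx = kxy(k, 0), cy = kxy(k, 1);
    double ang;
    if (forced) {
      ang = forced_angle[k];
    } else {
      if (!sample_pattern(img, cx, cy, pts, 0.0, vals)) { keep[k] = false; continue; }
      ang = pattern_orientation(vals, pts, opairs);
    }
    if (!sample_pattern(img, cx, cy, pts, ang, vals)) { keep[k] = false; continue; }
    keep[k] = true;
    angle[k] = ang;
    for (int b = 0; b < nb; ++b)
      bits(k, b) = (vals[pairs(b, 0)] - vals[pairs(b, 1)] > 0.0) ? 1 : 0;
  }
  return List::create(_["keep"] = keep, _["angle"] = angle, _["bits"] = bits);
}

// ---------------------------------------------------------------------------
// Brute-force Hamming matching: for each row of A the nearest row of B,
// ties broken by the lowest B index.  Bit rows are packed into 64-bit words.

static void pack_rows(IntegerMatrix& m, std::vector<uint64_t>& out, int words) {
  int n = m.nrow(), nb = m.ncol();
  std::fill(out.begin(), out.end(), 0);
  for (int i = 0; i < n; ++i)
    for (int b = 0; b < nb; ++b)
      if (m(i, b)) out[(size_t)i * words + b / 64] |= (uint64_t)1 << (b % 64);
}

// [[Rcpp::export]]
IntegerMatrix cf_hamming_match(IntegerMatrix A, IntegerMatrix B) {
  int na = A.nrow(), nbrows = B.nrow(), nb = A.ncol();
  if (B.ncol() != nb) stop("descriptor lengths differ");
  IntegerMatrix out(nbrows == 0 ? 0 : na, 2);
  if (nbrows == 0 || na == 0) return IntegerMatrix(0, 2);
  int words = (nb + 63) / 64;
  std::vector<uint64_t> pa((size_t)na * words), pb((size_t)nbrows * words);
  pack_rows(A, pa, words);
  pack_rows(B, pb, words);
  for (int i = 0; i < na; ++i) {
    int best = -1, bestd = nb + 1;
    for (int j = 0; j < nbrows; ++j) {
      int d = 0;
      for (int wrd = 0; wrd < words; ++wrd)
        d += __builtin_popcountll(pa[(size_t)i * words + wrd] ^ pb[(size_t)j * words + wrd]);
      if (d < bestd) { bestd = d; best = j; }
    }
    out(i, 0) = best + 1;
    out(i, 1) = bestd;
  }
  return out;
}
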