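#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear resampling, half-pixel-center convention:
// output pixel i maps to input coordinate (i + 0.5) * in/out - 0.5.
// Exact 2x reduction therefore equals 2x2 block averaging.
static void resize_bilinear_core(const double* in, int ih, int iw,
                                 double* out, int oh, int ow) {
  const double sr = static_cast<double>(ih) / oh;
  const double sc = static_cast<double>(iw) / ow;
  std::vector<int> c0(ow), c1(ow);
  std::vector<double> wc(ow);
  for (int j = 0; j < ow; ++j) {
    double x = (j + 0.5) * sc - 0.5;
    if (x < 0) x = 0;
    if (x > iw - 1) x = iw - 1;
    int j0 = static_cast<int>(std::floor(x));
    if (j0 > iw - 1) j0 = iw - 1;
    int j1 = j0 + 1 < iw ? j0 + 1 : iw - 1;
    c0[j] = j0; c1[j] = j1; wc[j] = x - j0;
  }
  for (int i = 0; i < oh; ++i) {
    double y = (i + 0.5) * sr - 0.5;
    if (y < 0) y = 0;
    if (y > ih - 1) y = ih - 1;
    int i0 = static_cast<int>(std::floor(y));
    if (i0 > ih - 1) i0 = ih - 1;
    int i1 = i0 + 1 < ih ? i0 + 1 : ih - 1;
    double wr = y - i0;
    for (int j = 0; j < ow; ++j) {
      double a = in[i0 + ih * c0[j]], b = in[i0 + ih * c1[j]];
      double c = in[i1 + ih * c0[j]], d = in[i1 + ih * c1[j]];
      double top = a + wc[j] * (b - a);
      double bot = c + wc[j] * (d - c);
      out[i + oh * j] = top + wr * (bot - top);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int out_h, int out_w) {
  if (out_h < 1 || out_w < 1) stop("target size must be positive");
  NumericMatrix out(out_h, out_w);
  resize_bilinear_core(img.begin(), img.nrow(), img.ncol(),
                       out.begin(), out_h, out_w);
  return out;
}

// HOG core on an image already at working size.
// Gradients: centered differences /2 on the interior, one-sided full
// differences at the borders. Orientation folded to [0, 180) degrees,
// magnitude votes linearly interpolated between the two nearest bin
// centers (centers at (b + 0.5) * 180/nbins, wrap-around). Cells are
// cell x cell px; blocks are block_cells x block_cells cells advancing by
// stride_px pixels; each block L2-normalized (eps = 1e-12 inside the root).
static void hog_core(const double* im, int h, int w,
                     int cell, int block_cells, int stride_px, int nbins,
                     std::vector<double>& feat) {
  const int nc_r = h / cell, nc_c = w / cell;
  const int stride_cells = stride_px / cell;
  const int nb_r = (nc_r - block_cells) / stride_cells + 1;
  const int nb_c = (nc_c - block_cells) / stride_cells + 1;
  const double binw = 180.0 / nbins;

  static std::vector<double> hist;   // reused across calls (R is
  static std::vector<double> block;  // single-threaded)
  hist.assign(static_cast<size_t>(nc_r) * nc_c * nbins, 0.0);
  for (int c = 0; c < nc_c * cell; ++c) {
    for (int r = 0; r < nc_r * cell; ++r) {
      double gx, gy;
      if (c == 0)          gx = im[r + h * 1] - im[r + h * 0];
      else if (c == w - 1) gx = im[r + h * (w - 1)] - im[r + h * (w - 2)];
      else                 gx = (im[r + h * (c + 1)] - im[r + h * (c - 1)]) / 2.0;
      if (r == 0)          gy = im[1 + h * c] - im[0 + h * c];
      else if (r == h - 1) gy = im[(h - 1) + h * c] - im[(h - 2) + h * c];
      else                 gy = (im[(r + 1) + h * c] - im[(r - 1) + h * c]) / 2.0;
      double mag = std::sqrt(gx * gx + gy * gy);
      if (mag == 0.0) continue;
      // unsigned orientation in [0, 180): atan(gy/gx) folded, which equals
      // atan2(gy, gx) mod 180 (gx == 0 gives +/-inf -> +/-90)
      double ang = std::atan(gy / gx) * 180.0 / M_PI;  // (-90, 90]
      if (ang < 0) ang += 180.0;
      if (ang >= 180.0) ang = 0.0;                     // guard rounding
      double t = ang / binw - 0.5;
      int b0 = static_cast<int>(std::floor(t));
      double w1 = t - b0;
      int bin0 = ((b0 % nbins) + nbins) % nbins;
      int bin1 = (bin0 + 1) % nbins;
      int ci = (r / cell) + nc_r * (c / cell);
      hist[ci * nbins + bin0] += mag * (1.0 - w1);
      hist[ci * nbins + bin1] += mag * w1;
    }
  }

  feat.assign(static_cast<size_t>(nb_r) * nb_c *
              block_cells * block_cells * nbins, 0.0);
  size_t k = 0;
  block.assign(block_cells * block_cells * nbins, 0.0);
  for (int br = 0; br < nb_r; ++br) {
    for (int bc = 0; bc < nb_c; ++bc) {
      size_t m = 0;
      double ss = 0.0;
      for (int i = 0; i < block_cells; ++i) {
        for (int j = 0; j < block_cells; ++j) {
          int ci = (br * stride_cells + i) + nc_r * (bc * stride_cells + j);
          for (int b = 0; b < nbins; ++b) {
            double v = hist[ci * nbins + b];
            block[m++] = v;
            ss += v * v;
          }
        }
      }
      double nrm = std::sqrt(ss + 1e-12);
      for (size_t q = 0; q < block.size(); ++q) feat[k++] = block[q] / nrm;
    }
  }
}

// [[Rcpp::export]]
NumericVector hog_cpp(NumericMatrix img, int cell, int block_cells,
                      int stride_px, int nbins) {
  int h = img.nrow(), w = img.ncol();
  if (cell < 1 || nbins < 1 || block_cells < 1) stop("invalid HOG geometry");
  if (stride_px % cell != 0) stop("block stride must be a multiple of cell size");
  int nc_r = h / cell, nc_c = w / cell, sc = stride_px / cell;
  if (nc_r < block_cells || nc_c < block_cells)
    stop("image smaller than one HOG block");
  if ((nc_r - block_cells) % sc != 0 || (nc_c - block_cells) % sc != 0) {
    // allowed: trailing cells simply unused by complete blocks
  }
  std::vector<double> feat;
  hog_core(img.begin(), h, w, cell, block_cells, stride_px, nbins, feat);
  return NumericVector(feat.begin(), feat.end());
}

// Sliding-window template matching: every stride-positioned window of size
// dr x dc is resized to rh x rw, HOG-described with the same parameters as
// the bank, and scored against each bank column by mean absolute difference.
// Returns the window minimizing MAD; ties broken by smallest row-major
// position, then smallest template index (strict < keeps the first).
// The window resize reads the source image in place through precomputed
// interpolation tables (same arithmetic as resize_bilinear_core), and the
// MAD accumulation aborts once it exceeds the current best -- both exact
// optimizations.
// [[Rcpp::export]]
List match_roi_cpp(NumericMatrix img, NumericMatrix bank_feat,
                   int dr, int dc, int rh, int rw,
                   int cell, int block_cells, int stride_px, int nbins,
                   int search_stride) {
  const int H = img.nrow(), W = img.ncol();
  if (dr > H || dc > W) stop("template larger than image");
  if (search_stride < 1) stop("search stride must be >= 1");
  const int T = bank_feat.ncol();
  const int hlen = bank_feat.nrow();

  // interpolation tables for the dr x dc -> rh x rw resize
  const double sr = static_cast<double>(dr) / rh;
  const double sc = static_cast<double>(dc) / rw;
  std::vector<int> r0(rh), r1(rh), c0(rw), c1(rw);
  std::vector<double> wrv(rh), wcv(rw);
  for (int i = 0; i < rh; ++i) {
    double y = (i + 0.5) * sr - 0.5;
    if (y < 0) y = 0;
    if (y > dr - 1) y = dr - 1;
    int i0 = static_cast<int>(std::floor(y));
    if (i0 > dr - 1) i0 = dr - 1;
    r0[i] = i0; r1[i] = i0 + 1 < dr ? i0 + 1 : dr - 1; wrv[i] = y - i0;
  }
  for (int j = 0; j < rw; ++j) {
    double x = (j + 0.5) * sc - 0.5;
    if (x < 0) x = 0;
    if (x > dc - 1) x = dc - 1;
    int j0 = static_cast<int>(std::floor(x));
    if (j0 > dc - 1) j0 = dc - 1;
    c0[j] = j0; c1[j] = j0 + 1 < dc ? j0 + 1 : dc - 1; wcv[j] = x - j0;
  }

  std::vector<double> rez(static_cast<size_t>(rh) * rw);
  std::vector<double> feat;
  double best = R_PosInf;
  int best_r = 0, best_c = 0, best_t = 0;

  for (int r = 0; r + dr <= H; r += search_stride) {
    for (int c = 0; c + dc <= W; c += search_stride) {
      const double* base = &img[r + H * c];
      for (int j = 0; j < rw; ++j) {
        const double* colA = base + static_cast<size_t>(H) * c0[j];
        const double* colB = base + static_cast<size_t>(H) * c1[j];
        const double wj = wcv[j];
        double* dst = &rez[static_cast<size_t>(rh) * j];
        for (int i = 0; i < rh; ++i) {
          double a = colA[r0[i]], b = colB[r0[i]];
          double cc = colA[r1[i]], d = colB[r1[i]];
          double top = a + wj * (b - a);
          double bot = cc + wj * (d - cc);
          dst[i] = top + wrv[i] * (bot - top);
        }
      }
      hog_core(rez.data(), rh, rw, cell, block_cells, stride_px, nbins, feat);
      if (static_cast<int>(feat.size()) != hlen)
        stop("bank feature length does not match HOG geometry");
      for (int t = 0; t < T; ++t) {
        const double* b = &bank_feat[static_cast<size_t>(hlen) * t];
        const double cutoff = best * hlen;
        double s = 0.0;
        int l = 0;
        for (; l < hlen; ++l) {
          s += std::fabs(feat[l] - b[l]);
          if (s >= cutoff) break;
        }
        if (l == hlen && s < cutoff) {
          best = s / hlen; best_r = r; best_c = c; best_t = t;
        }
      }
    }
  }
  return List::create(_["row"] = best_r, _["col"] = best_c,
                      _["score"] = best, _["template_index"] = best_t);
}
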