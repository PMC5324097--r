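#include <Rcpp.h>
using namespace Rcpp;

// Gaussian weight window, centred on the patch, sigma in pixels.
static NumericMatrix gauss_win(int n, double sigma, bool gaussian) {
  NumericMatrix w(n, n);
  double c = (n - 1) / 2.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      w(i, j) = gaussian
        ? std::exp(-((i - c) * (i - c) + (j - c) * (j - c)) /
                   (2.0 * sigma * sigma))
        : 1.0;
  return w;
}

// Normalized weighted SSD between the filled part of the target window at
// (r0, c0) and the source window at (sr, sc); mask(i,j) marks filled pixels.
static double masked_ssd(const NumericMatrix &out, const LogicalMatrix &mask,
                         int r0, int c0, const NumericMatrix &src,
                         int sr, int sc, int n, const NumericMatrix &w) {
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (mask(r0 + i, c0 + j)) {
        double d = out(r0 + i, c0 + j) - src(sr + i, sc + j);
        num += w(i, j) * d * d;
        den += w(i, j);
      }
  return den > 0 ? num / den : 0.0;
}

// Tolerance-based candidate draw shared by both modes: collect indices with
// d <= (1 + eps) * dmin (with a hair of floating slack) and pick uniformly.
static int draw_candidate(const std::vector<double> &d, double eps,
                          double &dmin_out) {
  double dmin = d[0];
  for (size_t k = 1; k < d.size(); ++k) if (d[k] < dmin) dmin = d[k];
  double thr = (1.0 + eps) * dmin + 1e-12 * (1.0 + dmin);
  std::vector<int> cand;
  for (size_t k = 0; k < d.size(); ++k) if (d[k] <= thr) cand.push_back(k);
  dmin_out = dmin;
  int pick = (int)std::floor(unif_rand() * cand.size());
  if (pick >= (int)cand.size()) pick = cand.size() - 1;
  return cand[pick];
}

// Patch-based engine: raster placement of n x n source windows overlapping
// previously synthesized content by `overlap` pixels; each patch drawn
// uniformly from the candidate set scored on the overlap region.
// [[Rcpp::export]]
List synth_patch_cpp(NumericMatrix source, int n, int overlap,
                     int outH, int outW, double eps, double sigma,
                     bool gaussian) {
  RNGScope scope;
  int Hs = source.nrow(), Ws = source.ncol();
  int nwr = Hs - n + 1, nwc = Ws - n + 1;
  int nw = nwr * nwc;
  NumericMatrix w = gauss_win(n, sigma, gaussian);
  NumericMatrix out(outH, outW);
  LogicalMatrix filled(outH, outW);
  int step = n - overlap;

  std::vector<int> rows, cols;
  for (int r = 0; r + n <= outH; r += step) rows.push_back(r);
  if (rows.back() != outH - n) rows.push_back(outH - n);
  for (int c = 0; c + n <= outW; c += step) cols.push_back(c);
  if (cols.back() != outW - n) cols.push_back(outW - n);

  int nplace = rows.size() * cols.size();
  NumericVector d_chosen(nplace), d_min(nplace);
  std::vector<double> d(nw);
  int stepi = 0;
  for (size_t ri = 0; ri < rows.size(); ++ri) {
    for (size_t ci = 0; ci < cols.size(); ++ci, ++stepi) {
      int r0 = rows[ri], c0 = cols[ci];
      bool any_filled = false;
      for (int i = 0; i < n && !any_filled; ++i)
        for (int j = 0; j < n; ++j)
          if (filled(r0 + i, c0 + j)) { any_filled = true; break; }
      int pick;
      if (!any_filled) {               // first patch: uniform over windows
        pick = (int)std::floor(unif_rand() * nw);
        if (pick >= nw) pick = nw - 1;
        d_chosen[stepi] = 0.0; d_min[stepi] = 0.0;
      } else {
        for (int k = 0; k < nw; ++k)
          d[k] = masked_ssd(out, filled, r0, c0, source,
                            k % nwr, k / nwr, n, w);
        double dmin;
        pick = draw_candidate(d, eps, dmin);
        d_chosen[stepi] = d[pick]; d_min[stepi] = dmin;
      }
      int sr = pick % nwr, sc = pick / nwr;
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          out(r0 + i, c0 + j) = source(sr + i, sc + j);
          filled(r0 + i, c0 + j) = true;
        }
    }
  }
  return List::create(_["pixels"] = out, _["d_chosen"] = d_chosen,
                      _["d_min"] = d_min);
}

// Per-pixel engine: seed block at the top-left, then raster filling of the
// remaining pixels, each drawn from the candidate set of source windows
// scored on the already-filled part of its centred neighbourhood.
// [[Rcpp::export]]
List synth_pixel_cpp(NumericMatrix source, int n, int outH, int outW,
                     double eps, double sigma, bool gaussian) {
  RNGScope scope;
  int Hs = source.nrow(), Ws = source.ncol();
  int half = n / 2;
  int win = 2 * half + 1;                 // odd neighbourhood
  NumericMatrix w = gauss_win(win, sigma, gaussian);
  // candidate centres must have a full neighbourhood inside the source
  int ncr = Hs - 2 * half, ncc = Ws - 2 * half;
  int nc = ncr * ncc;
  NumericMatrix out(outH, outW);
  LogicalMatrix filled(outH, outW);

  // seed: copy one uniformly chosen n x n window to the top-left corner
  int nwr = Hs - n + 1, nwc = Ws - n + 1;
  int seed = (int)std::floor(unif_rand() * (nwr * nwc));
  if (seed >= nwr * nwc) seed = nwr * nwc - 1;
  int sr = seed % nwr, sc = seed / nwr;
  for (int i = 0; i < n && i < outH; ++i)
    for (int j = 0; j < n && j < outW; ++j) {
      out(i, j) = source(sr + i, sc + j);
      filled(i, j) = true;
    }

  std::vector<double> d(nc);
  for (int r = 0; r < outH; ++r)
    for (int c = 0; c < outW; ++c) {
      if (filled(r, c)) continue;
      for (int k = 0; k < nc; ++k) {
        int cr = k % ncr + half, cc = k / ncr + half;
        double num = 0.0, den = 0.0;
        for (int i = -half; i <= half; ++i)
          for (int j = -half; j <= half; ++j) {
            int tr = r + i, tc = c + j;
            if (tr < 0 || tr >= outH || tc < 0 || tc >= outW) continue;
            if (!filled(tr, tc)) continue;
            double diff = out(tr, tc) - source(cr + i, cc + j);
            num += w(i + half, j + half) * diff * diff;
            den += w(i + half, j + half);
          }
        d[k] = den > 0 ? num / den : 0.0;
      }
      double dmin;
      int pick = draw_candidate(d, eps, dmin);
      out(r, c) = source(pick % ncr + half, pick / ncr + half);
      filled(r, c) = true;
    }
  return List::create(_["pixels"] = out);
}
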