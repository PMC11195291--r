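#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// One-dimensional Gaussian factors exp(-(x-mu)^2 / (2 sigma^2)) at grid
// coordinates.  Values beyond `cutoff` (in the same units as xs) are set to
// exactly zero so that a finite cutoff gives a deterministic truncated
// Gaussian rather than a grid-order-dependent approximation.
static void gauss1d(const NumericVector& xs, double mu, double two_s2,
                    double cutoff, std::vector<double>& e) {
  const int n = xs.size();
  e.resize(n);
  for (int i = 0; i < n; ++i) {
    double d = xs[i] - mu;
    e[i] = (std::fabs(d) > cutoff) ? 0.0 : std::exp(-d * d / two_s2);
  }
}

// Causal discrete convolution truncated to the input length:
// y[n] = sum_{j=0}^{min(n, m-1)} x[n-j] * k[j].
static void conv_causal(const double* x, int n, const NumericVector& k,
                        double* y) {
  const int m = k.size();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const int jmax = std::min(i, m - 1);
    for (int j = 0; j <= jmax; ++j) s += x[i - j] * k[j];
    y[i] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_convolve_causal(NumericVector x, NumericVector kernel) {
  NumericVector y(x.size());
  conv_causal(x.begin(), x.size(), kernel, y.begin());
  return y;
}

// Spatial overlap of Gaussian pRFs with a sparse aperture movie.
//
// frame_ptr: length nt+1, 0-based cumulative counts of active pixels per
//            frame; idx: 0-based column-major pixel indices (row = idx % ny,
//            col = idx / ny); wt: pixel weight (1 for binary apertures,
//            fractional coverage otherwise).  xs/ys: pixel-center coordinates
//            in degrees for columns/rows.  frame bounding boxes (row_lo..,
//            0-based) allow skipping frames that cannot intersect the
//            truncated Gaussian when cutoff_sigmas is finite.
// [[Rcpp::export]]
NumericMatrix cpp_overlap_many(IntegerVector frame_ptr, IntegerVector idx,
                               NumericVector wt, NumericVector xs,
                               NumericVector ys, NumericVector mu_x,
                               NumericVector mu_y, NumericVector sigma,
                               IntegerVector row_lo, IntegerVector row_hi,
                               IntegerVector col_lo, IntegerVector col_hi,
                               double cutoff_sigmas) {
  const int nt = frame_ptr.size() - 1;
  const int ny = ys.size();
  const int np = mu_x.size();
  const bool finite_cut = R_finite(cutoff_sigmas);
  NumericMatrix out(nt, np);
  std::vector<double> ex, ey;

  for (int p = 0; p < np; ++p) {
    const double sg = sigma[p];
    const double two_s2 = 2.0 * sg * sg;
    const double cut = finite_cut ? cutoff_sigmas * sg : R_PosInf;
    gauss1d(xs, mu_x[p], two_s2, cut, ex);
    gauss1d(ys, mu_y[p], two_s2, cut, ey);
    double* o = &out(0, p);
    for (int t = 0; t < nt; ++t) {
      const int a = frame_ptr[t], b = frame_ptr[t + 1];
      if (a == b) continue;
      if (finite_cut) {
        // ys runs top-down (descending); xs ascending
        const double fx0 = xs[col_lo[t]], fx1 = xs[col_hi[t]];
        const double fy1 = ys[row_lo[t]], fy0 = ys[row_hi[t]];
        if (fx0 > mu_x[p] + cut || fx1 < mu_x[p] - cut ||
            fy0 > mu_y[p] + cut || fy1 < mu_y[p] - cut)
          continue;
      }
      double s = 0.0;
      for (int q = a; q < b; ++q) {
        const int u = idx[q];
        s += wt[q] * ex[u / ny] * ey[u % ny];
      }
      o[t] = s;
    }
  }
  return out;
}

// Run-length-encoded overlap for binary apertures. Active pixels of each
// frame are stored as vertical runs (column, row_lo..row_hi inclusive,
// 0-based); the Gaussian row sum over a run is a prefix-sum difference, so
// the cost per frame is the number of runs, not the number of pixels.
// [[Rcpp::export]]
NumericMatrix cpp_overlap_runs(IntegerVector run_ptr, IntegerVector run_col,
                               IntegerVector run_lo, IntegerVector run_hi,
                               NumericVector xs, NumericVector ys,
                               NumericVector mu_x, NumericVector mu_y,
                               NumericVector sigma, IntegerVector frow_lo,
                               IntegerVector frow_hi, IntegerVector fcol_lo,
                               IntegerVector fcol_hi, double cutoff_sigmas) {
  const int nt = run_ptr.size() - 1;
  const int ny = ys.size();
  const int np = mu_x.size();
  const bool finite_cut = R_finite(cutoff_sigmas);
  NumericMatrix out(nt, np);
  std::vector<double> ex, ey, cum(ny + 1);

  for (int p = 0; p < np; ++p) {
    const double sg = sigma[p];
    const double two_s2 = 2.0 * sg * sg;
    const double cut = finite_cut ? cutoff_sigmas * sg : R_PosInf;
    gauss1d(xs, mu_x[p], two_s2, cut, ex);
    gauss1d(ys, mu_y[p], two_s2, cut, ey);
    cum[0] = 0.0;
    for (int r = 0; r < ny; ++r) cum[r + 1] = cum[r] + ey[r];
    double* o = &out(0, p);
    for (int t = 0; t < nt; ++t) {
      const int a = run_ptr[t], b = run_ptr[t + 1];
      if (a == b) continue;
      if (finite_cut) {
        const double fx0 = xs[fcol_lo[t]], fx1 = xs[fcol_hi[t]];
        const double fy1 = ys[frow_lo[t]], fy0 = ys[frow_hi[t]];
        if (fx0 > mu_x[p] + cut || fx1 < mu_x[p] - cut ||
            fy0 > mu_y[p] + cut || fy1 < mu_y[p] - cut)
          continue;
      }
      double s = 0.0;
      for (int q = a; q < b; ++q) {
        const double g = ex[run_col[q]];
        if (g == 0.0) continue;
        s += g * (cum[run_hi[q] + 1] - cum[run_lo[q]]);
      }
      o[t] = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_runs(IntegerVector run_ptr, IntegerVector run_col,
                               IntegerVector run_lo, IntegerVector run_hi,
                               NumericVector xs, NumericVector ys,
                               NumericVector mu_x, NumericVector mu_y,
                               NumericVector sigma, IntegerVector frow_lo,
                               IntegerVector frow_hi, IntegerVector fcol_lo,
                               IntegerVector fcol_hi, NumericVector kernel,
                               double cutoff_sigmas) {
  NumericMatrix O = cpp_overlap_runs(run_ptr, run_col, run_lo, run_hi, xs,
                                     ys, mu_x, mu_y, sigma, frow_lo, frow_hi,
                                     fcol_lo, fcol_hi, cutoff_sigmas);
  const int nt = O.nrow(), np = O.ncol();
  NumericMatrix out(nt, np);
  std::vector<double> tmp(nt);
  for (int p = 0; p < np; ++p) {
    conv_causal(&O(0, p), nt, kernel, tmp.data());
    std::copy(tmp.begin(), tmp.end(), &out(0, p));
  }
  return out;
}

// Predicted time courses: overlap traces convolved with an HRF kernel.
// Returns an nt x np matrix, one column per pRF.
// [[Rcpp::export]]
NumericMatrix cpp_predict_many(IntegerVector frame_ptr, IntegerVector idx,
                               NumericVector wt, NumericVector xs,
                               NumericVector ys, NumericVector mu_x,
                               NumericVector mu_y, NumericVector sigma,
                               IntegerVector row_lo, IntegerVector row_hi,
                               IntegerVector col_lo, IntegerVector col_hi,
                               NumericVector kernel, double cutoff_sigmas) {
  NumericMatrix O = cpp_overlap_many(frame_ptr, idx, wt, xs, ys, mu_x, mu_y,
                                     sigma, row_lo, row_hi, col_lo, col_hi,
                                     cutoff_sigmas);
  const int nt = O.nrow(), np = O.ncol();
  NumericMatrix out(nt, np);
  std::vector<double> tmp(nt);
  for (int p = 0; p < np; ++p) {
    conv_causal(&O(0, p), nt, kernel, tmp.data());
    std::copy(tmp.begin(), tmp.end(), &out(0, p));
  }
  return out;
}

// Pearson correlation of a candidate prediction against a pre-standardized
// data vector dz (centered, unit sum of squares).  Returns NA when the
// prediction has zero variance.
// [[Rcpp::export]]
double cpp_cor_z(NumericVector pred, NumericVector dz) {
  const int n = pred.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += pred[i];
  mean /= n;
  double num = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) {
    const double c = pred[i] - mean;
    num += c * dz[i];
    ss += c * c;
  }
  if (ss <= 0.0) return NA_REAL;
  return num / std::sqrt(ss);
}
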