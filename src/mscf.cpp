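// Maximum-symmetry center-frequency (MSCF) search for WASSR B0 mapping.
//
// Input: per-voxel spectra evaluated on a symmetric regular offset grid
// (rows = voxels). For each voxel the center c minimizing the symmetry
// error  E(c) = sum_d ( Z(c+d) - Z(c-d) )^2  over a fixed window of
// mirrored grid shifts d = 1..D is found by a coarse-then-fine index
// search, followed by parabolic interpolation of E around the best index.
// Returns the fractional center index (0-based, relative to the grid).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double sym_err(const rowvec& z, int c, int D) {
  double e = 0.0;
  for (int d = 1; d <= D; ++d) {
    double diff = z(c + d) - z(c - d);
    e += diff * diff;
  }
  return e;
}

// [[Rcpp::export]]
arma::vec mscf_center_cpp(const arma::mat& zgrid, int center, int max_shift,
                          int coarse_step) {
  int n = zgrid.n_cols;
  int D = std::min(center - max_shift, n - 1 - center - max_shift);
  if (D < 3) Rcpp::stop("search window too wide for the offset grid");
  vec out(zgrid.n_rows);
  for (uword v = 0; v < zgrid.n_rows; ++v) {
    rowvec z = zgrid.row(v);
    // coarse pass
    int best = center;
    double ebest = datum::inf;
    for (int c = center - max_shift; c <= center + max_shift; c += coarse_step) {
      double e = sym_err(z, c, D);
      if (e < ebest) { ebest = e; best = c; }
    }
    // fine pass around the coarse minimum
    int lo = std::max(center - max_shift, best - coarse_step);
    int hi = std::min(center + max_shift, best + coarse_step);
    for (int c = lo; c <= hi; ++c) {
      double e = sym_err(z, c, D);
      if (e < ebest) { ebest = e; best = c; }
    }
    // parabolic refinement on the fine grid
    double delta = 0.0;
    if (best > center - max_shift && best < center + max_shift) {
      double em = sym_err(z, best - 1, D);
      double ep = sym_err(z, best + 1, D);
      double denom = em - 2.0 * ebest + ep;
      if (denom > 0) {
        delta = 0.5 * (em - ep) / denom;
        if (delta > 1.0) delta = 1.0;
        if (delta < -1.0) delta = -1.0;
      }
    }
    out(v) = best + delta;
  }
  return out;
}
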