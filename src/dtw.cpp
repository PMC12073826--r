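#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Classic dynamic time warping with absolute-difference local cost and
// unit steps (match / insert / delete).  band < 0 means unconstrained;
// band >= 0 is a Sakoe-Chiba band on the index difference.
static double dtw_pair(const double *a, int na, const double *b, int nb,
                       int band) {
  std::vector<double> prev(nb + 1, R_PosInf), cur(nb + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= na; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = 1, jhi = nb;
    if (band >= 0) {
      // centre the band on the diagonal scaled for unequal lengths
      double c = (double)i * nb / na;
      jlo = std::max(1, (int)std::floor(c - band));
      jhi = std::min(nb, (int)std::ceil(c + band));
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".dtw_dist_cpp")]]
double dtw_dist_cpp(NumericVector a, NumericVector b, int band) {
  if (a.size() == 0 || b.size() == 0)
    stop("dtw_distance: empty input sequence");
  return dtw_pair(REAL(a), a.size(), REAL(b), b.size(), band);
}

// Pairwise distances between the rows of two matrices.
// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(NumericMatrix x, NumericMatrix y, int band) {
  int nx = x.nrow(), ny = y.nrow(), p = x.ncol(), q = y.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> xi(p), yj(q);
  for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < p; ++k) xi[k] = x(i, k);
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < q; ++k) yj[k] = y(j, k);
      out(i, j) = dtw_pair(xi.data(), p, yj.data(), q, band);
    }
  }
  return out;
}
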