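#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour search and divergence tracking for the Rosenstein
// maximal-Lyapunov-exponent estimator.
//
// X:        attractor matrix, one delay vector per row
// theiler:  half-window of temporally adjacent rows excluded from the
//           neighbour search (|i - j| <= theiler is skipped)
// t_max:    number of samples to track each pair forward
//
// For every row j the Euclidean nearest neighbour nn(j) is found (ties
// broken toward the smaller row index, so results are bit-reproducible).
// For t = 0..t_max the mean over j of log ||X[j+t] - X[nn(j)+t]|| is
// accumulated; pairs whose track leaves the data are dropped from the mean
// at that t.  Exact zero distances are counted and later replaced by the
// smallest positive distance seen anywhere on the curve (log of zero is
// undefined; the substitution floor is reported to the caller).
// [[Rcpp::export(name = ".gv_rosenstein_cpp")]]
List gv_rosenstein(NumericMatrix X, int theiler, int t_max) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<int> nn(n, -1);

  // column-major access: cache the matrix as contiguous rows
  std::vector<double> A((size_t)n * m);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < m; ++k)
      A[(size_t)j * m + k] = X(j, k);

  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    int besti = -1;
    const double *xj = &A[(size_t)j * m];
    const int lo_end = j - theiler;        // exclusive upper bound, left side
    const int hi_beg = j + theiler + 1;    // inclusive lower bound, right side
    for (int i = 0; i < lo_end; ++i) {
      const double *xi = &A[(size_t)i * m];
      double d2 = 0.0;
      int k = 0;
      for (; k < m; ++k) {
        const double dd = xj[k] - xi[k];
        d2 += dd * dd;
        if (d2 >= best) break;             // early abandon
      }
      if (k == m && d2 < best) { best = d2; besti = i; }
    }
    for (int i = hi_beg; i < n; ++i) {
      const double *xi = &A[(size_t)i * m];
      double d2 = 0.0;
      int k = 0;
      for (; k < m; ++k) {
        const double dd = xj[k] - xi[k];
        d2 += dd * dd;
        if (d2 >= best) break;
      }
      if (k == m && d2 < best) { best = d2; besti = i; }  // ties keep smaller i
    }
    nn[j] = besti;
  }

  std::vector<double> sumlog(t_max + 1, 0.0);
  std::vector<int> count(t_max + 1, 0), nzero(t_max + 1, 0);
  double minpos2 = R_PosInf;

  for (int j = 0; j < n; ++j) {
    const int i = nn[j];
    if (i < 0) continue;
    const int tlim = std::min(t_max, n - 1 - std::max(i, j));
    for (int t = 0; t <= tlim; ++t) {
      const double *xj = &A[(size_t)(j + t) * m];
      const double *xi = &A[(size_t)(i + t) * m];
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double dd = xj[k] - xi[k];
        d2 += dd * dd;
      }
      if (d2 > 0.0) {
        sumlog[t] += 0.5 * std::log(d2);
        count[t] += 1;
        if (d2 < minpos2) minpos2 = d2;
      } else {
        nzero[t] += 1;
      }
    }
  }

  const double logfloor = R_FINITE(minpos2) ? 0.5 * std::log(minpos2) : NA_REAL;
  NumericVector d(t_max + 1);
  IntegerVector npairs(t_max + 1);
  int total_zero = 0;
  for (int t = 0; t <= t_max; ++t) {
    const int c = count[t] + nzero[t];
    npairs[t] = c;
    total_zero += nzero[t];
    d[t] = (c > 0) ? (sumlog[t] + nzero[t] * logfloor) / c : NA_REAL;
  }

  IntegerVector nn_out(n);
  for (int j = 0; j < n; ++j) nn_out[j] = nn[j] + 1;  // 1-based for R

  return List::create(_["d"] = d, _["n_pairs"] = npairs, _["nn"] = nn_out,
                      _["n_zero_replaced"] = total_zero,
                      _["dist_floor"] = R_FINITE(minpos2) ?
                          std::sqrt(minpos2) : NA_REAL);
}
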