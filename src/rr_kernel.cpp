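#include <Rcpp.h>
using namespace Rcpp;

// Mean over intra-population variability draws of the piecewise log-linear
// relative risk, per stratum and uncertainty draw.
//
//   ceq : strata x n_variability matrix of equivalent ambient NO2 (ppb)
//   b   : log(RR0_u) / delta_C0 per uncertainty draw (ppb^-1)
//   lc  : low-concentration threshold per uncertainty draw (ppb)
//
// Returns a strata x n_uncertainty matrix of averaged relative risks.
// Loop order (uncertainty, variability, strata) keeps both the read of ceq
// and the write of the output column-contiguous; the working set is one
// output column, so memory stays proportional to strata count.
// [[Rcpp::export]]
NumericMatrix rr_pop_mean_cpp(NumericMatrix ceq, NumericVector b,
                              NumericVector lc) {
  const int g = ceq.nrow();
  const int v = ceq.ncol();
  const int u = b.size();
  if (lc.size() != u) stop("b and lc must have equal length");
  NumericMatrix out(g, u);
  const double *x = ceq.begin();
  for (int j = 0; j < u; ++j) {
    const double bj = b[j];
    const double lj = lc[j];
    double *col = &out(0, j);
    for (int k = 0; k < v; ++k) {
      const double *xk = x + (std::size_t)k * g;
      for (int i = 0; i < g; ++i) {
        const double e = xk[i] - lj;
        col[i] += (e > 0.0) ? std::exp(bj * e) : 1.0;
      }
    }
    const double inv = 1.0 / v;
    for (int i = 0; i < g; ++i) col[i] *= inv;
  }
  return out;
}
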