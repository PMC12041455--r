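#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with zero initial conditions.
// Coefficients must be normalized so a[0] == 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int m = std::max(na, nb) - 1;
  std::vector<double> d(m, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (m > 0 ? d[0] : 0.0);
    for (int k = 0; k < m; ++k) {
      const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      d[k] = bk * xi - ak * yi + (k + 1 < m ? d[k + 1] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}
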