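#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter: a[0]*y[n] = sum b[k] x[n-k] - sum a[k] y[n-k]
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), w(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + w[0];
    for (int k = 0; k < nw - 1; ++k)
      w[k] = bb[k + 1] * xi - aa[k + 1] * yi + w[k + 1];
    y[i] = yi;
  }
  return y;
}
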