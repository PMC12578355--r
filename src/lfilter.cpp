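#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial conditions.
// b, a are transfer-function coefficients with a[0] == 1 (caller normalises);
// zi has length max(length(a), length(b)) - 1.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(nb, na);
  int nz = n - 1;
  if (zi.size() != nz) stop("zi must have length max(length(a), length(b)) - 1");
  std::vector<double> bb(n, 0.0), aa(n, 0.0), z(nz);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < nz; ++i) z[i] = zi[i];
  int len = x.size();
  NumericVector y(len);
  for (int m = 0; m < len; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + (nz > 0 ? z[0] : 0.0);
    for (int i = 0; i < nz - 1; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    if (nz > 0) z[nz - 1] = bb[n - 1] * xm - aa[n - 1] * ym;
    y[m] = ym;
  }
  return y;
}
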