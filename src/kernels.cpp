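#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dilated convolution features for random kernels: for each kernel, the
// maximum of the convolution output and the proportion of positive values.
// Signals are assumed already z-scored by the caller. Zero padding of
// ((len-1)*dilation)/2 on each side when padding is set; "valid"
// convolution otherwise. Tap-major accumulation keeps the inner loop
// branch-free.
// [[Rcpp::export]]
NumericVector rocket_features_cpp(NumericVector x, List weights,
                                  NumericVector bias, IntegerVector dilation,
                                  LogicalVector padding) {
  const int n = x.size();
  const double *xs = x.begin();
  const int K = weights.size();
  NumericVector out(2 * K);
  std::vector<double> buf;
  for (int k = 0; k < K; ++k) {
    NumericVector w = weights[k];
    const int len = w.size();
    const int dil = dilation[k];
    const double b = bias[k];
    const int pad = padding[k] ? ((len - 1) * dil) / 2 : 0;
    const int out_len = n + 2 * pad - (len - 1) * dil;
    if (out_len < 1) {
      // receptive field wider than the (clipped) signal: the only defined
      // output is the bias alone
      out[2 * k] = b;
      out[2 * k + 1] = b > 0 ? 1.0 : 0.0;
      continue;
    }
    buf.assign(out_len, b);
    for (int j = 0; j < len; ++j) {
      const double wj = w[j];
      const int off = j * dil - pad;          // x index for output 0
      const int i0 = std::max(0, -off);
      const int i1 = std::min(out_len, n - off);
      const double *xp = xs + i0 + off;
      double *bp = buf.data() + i0;
      for (int i = i0; i < i1; ++i) *bp++ += wj * *xp++;
    }
    double mx = buf[0];
    int pos = 0;
    for (int i = 0; i < out_len; ++i) {
      if (buf[i] > mx) mx = buf[i];
      if (buf[i] > 0) ++pos;
    }
    out[2 * k] = mx;
    out[2 * k + 1] = (double)pos / out_len;
  }
  return out;
}
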