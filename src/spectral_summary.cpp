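#include <Rcpp.h>
using namespace Rcpp;

// Column-wise spectral descriptors from a one-sided power matrix (bins x
// windows): power-weighted mean frequency, index of the median-frequency bin
// (first bin where cumulative power reaches half the total; 0 when the
// spectrum is all zero), and the peak value and its bin index.
// [[Rcpp::export(name = ".spectral_summary_cpp")]]
NumericMatrix spectral_summary(const NumericMatrix &P,
                               const NumericVector &freq) {
  const int M = P.nrow(), m = P.ncol();
  NumericMatrix out(m, 4);
  colnames(out) = CharacterVector::create("MNF", "MDF_IDX", "PKF_MAX",
                                          "PKF_IDX");
  for (int j = 0; j < m; ++j) {
    long double tot = 0, wsum = 0;
    double mx = P(0, j);
    int mxi = 0;
    for (int i = 0; i < M; ++i) {
      const double p = P(i, j);
      tot += p;
      wsum += p * freq[i];
      if (p > mx) {
        mx = p;
        mxi = i;
      }
    }
    double mnf = 0;
    int mdf_idx = 0;
    if (tot > 0) {
      mnf = (double)(wsum / tot);
      long double cum = 0;
      const long double half = tot / 2;
      for (int i = 0; i < M; ++i) {
        cum += P(i, j);
        if (cum >= half) {
          mdf_idx = i + 1;  // 1-based bin index
          break;
        }
      }
    }
    out(j, 0) = mnf;
    out(j, 1) = mdf_idx;
    out(j, 2) = mx;
    out(j, 3) = mxi + 1;
  }
  return out;
}
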