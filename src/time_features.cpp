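#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted buffer.
static double quantile7(const std::vector<double> &s, double p) {
  const int n = s.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// All time-domain features for a block of equal-length windows (one window
// per column). Spectral descriptors (MNF/MDF/PKF) are computed in R from the
// FFT. Column order matches the names vector returned alongside.
// [[Rcpp::export(name = ".time_features_block_cpp")]]
NumericMatrix time_features_block(const NumericMatrix &S, double zc_thr,
                                  double ssc_thr, double wamp_thr,
                                  double v_order, int entropy_bins,
                                  int mmav_literature, double kurt_offset) {
  const int N = S.nrow(), m = S.ncol();
  if (N < 2) stop("windows must have >= 2 samples");
  const int NF = 34;
  NumericMatrix out(m, NF);
  CharacterVector nm = CharacterVector::create(
      "KURT", "SKEW", "SSI", "SD", "RMS", "ENTROPY", "MAV", "AAC", "DASDV",
      "LD", "MMAV1", "MMAV2", "SSC", "WAMP", "WL", "VAR", "RSSQ", "P2P",
      "BP", "TM3", "TM5", "V0", "MAD0", "MAD1", "IEMG", "MAXAV", "ZC",
      "AVSER", "AVSSR", "COV", "DAMV", "IQR", "MVSR", "MINAV");
  colnames(out) = nm;

  // MMAV weight vectors (1-based sample index i over window length L = N).
  std::vector<double> w1(N), w2(N);
  for (int i = 1; i <= N; ++i) {
    bool mid = (i >= 0.25 * N && i <= 0.75 * N);
    w1[i - 1] = mid ? 1.0 : 0.5;
    if (mid) w2[i - 1] = 1.0;
    else if (i < 0.25 * N) w2[i - 1] = 4.0 * i / N;
    else w2[i - 1] = mmav_literature ? 4.0 * (N - i) / N : 0.5;
  }
  const double inv_e = 1.0 / std::exp(1.0);
  const int v_int = (v_order == std::floor(v_order) && v_order > 0 &&
                     v_order <= 8) ? (int)v_order : 0;
  std::vector<double> buf(N);
  std::vector<int> hist(entropy_bins);

  for (int j = 0; j < m; ++j) {
    const double *x = &S(0, j);
    long double s1 = 0, s2 = 0, s3 = 0, s5 = 0, sa = 0, ssq = 0, ser = 0,
                sv = 0, slog = 0, w1s = 0, w2s = 0;
    double mn = x[0], mx = x[0], minav = std::fabs(x[0]),
           maxav = std::fabs(x[0]);
    for (int i = 0; i < N; ++i) {
      const double xi = x[i], a = std::fabs(xi);
      if (!std::isfinite(xi)) stop("non-finite samples in window block");
      s1 += xi;
      s2 += xi * xi;
      s3 += xi * xi * xi;
      s5 += xi * xi * xi * xi * xi;
      sa += a;
      ssq += std::sqrt(a);
      ser += std::pow(a, inv_e);
      if (v_int) {
        double av = a;
        for (int q = 1; q < v_int; ++q) av *= a;
        sv += av;
      } else {
        sv += std::pow(a, v_order);
      }
      slog += std::log(a > 1e-12 ? a : 1e-12);
      w1s += w1[i] * a;
      w2s += w2[i] * a;
      if (xi < mn) mn = xi;
      if (xi > mx) mx = xi;
      if (a < minav) minav = a;
      if (a > maxav) maxav = a;
    }
    long double wl = 0, dsq = 0;
    int wamp = 0, zc = 0, ssc = 0;
    for (int i = 0; i < N - 1; ++i) {
      const double d = x[i + 1] - x[i], ad = std::fabs(d);
      wl += ad;
      dsq += d * d;
      if (ad > wamp_thr) ++wamp;
      if (x[i] * x[i + 1] < 0 && ad >= zc_thr) ++zc;
    }
    for (int i = 1; i < N - 1; ++i)
      if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > ssc_thr) ++ssc;

    const double mu = (double)(s1 / N);
    long double sy2 = 0, sy3 = 0, sy4 = 0, sad = 0;
    for (int i = 0; i < N; ++i) {
      const double y = x[i] - mu, y2 = y * y;
      sy2 += y2;
      sy3 += y2 * y;
      sy4 += y2 * y2;
      sad += std::fabs(y);
    }
    const double m2 = (double)(sy2 / N);
    const double sdv = std::sqrt((double)(sy2 / (N - 1)));

    std::copy(x, x + N, buf.begin());
    std::sort(buf.begin(), buf.end());
    const double q25 = quantile7(buf, 0.25), med = quantile7(buf, 0.5),
                 q75 = quantile7(buf, 0.75);
    long double sadm = 0;
    for (int i = 0; i < N; ++i) sadm += std::fabs(x[i] - med);

    double ent = 0;
    const double rng = mx - mn;
    if (rng > 0) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int i = 0; i < N; ++i) {
        int b = (int)std::floor((x[i] - mn) / rng * entropy_bins);
        if (b >= entropy_bins) b = entropy_bins - 1;
        ++hist[b];
      }
      for (int b = 0; b < entropy_bins; ++b)
        if (hist[b] > 0) {
          const double p = (double)hist[b] / N;
          ent -= p * std::log(p);
        }
    }

    double cov = 0;
    if (sdv > 0) {
      double mf = mu;
      const double fl = 1e-12 * sdv;
      if (std::fabs(mf) < fl) mf = (mf < 0) ? -fl : fl;
      cov = 100.0 * sdv / mf;
    }

    int c = 0;
    out(j, c++) = m2 > 0 ? (double)(sy4 / N) / (m2 * m2) - kurt_offset : 0.0;
    out(j, c++) = m2 > 0 ? (double)(sy3 / N) / std::pow(m2, 1.5) : 0.0;
    out(j, c++) = (double)s2;                            // SSI
    out(j, c++) = sdv;                                   // SD
    out(j, c++) = std::sqrt((double)(s2 / N));           // RMS
    out(j, c++) = ent;                                   // ENTROPY
    out(j, c++) = (double)(sa / N);                      // MAV
    out(j, c++) = (double)(wl / N);                      // AAC
    out(j, c++) = std::sqrt((double)(dsq / (N - 1)));    // DASDV
    out(j, c++) = std::exp((double)(slog / N));          // LD
    out(j, c++) = (double)(w1s / N);                     // MMAV1
    out(j, c++) = (double)(w2s / N);                     // MMAV2
    out(j, c++) = ssc;                                   // SSC
    out(j, c++) = wamp;                                  // WAMP
    out(j, c++) = (double)wl;                            // WL
    out(j, c++) = (double)(s2 / (N + 1));                // VAR
    out(j, c++) = std::sqrt((double)s2);                 // RSSQ
    out(j, c++) = mx - mn;                               // P2P
    out(j, c++) = (double)(s2 / N);                      // BP
    out(j, c++) = std::fabs((double)(s3 / N));           // TM3
    out(j, c++) = std::fabs((double)(s5 / N));           // TM5
    out(j, c++) = std::pow((double)(sv / N), 1.0 / v_order);  // V0
    out(j, c++) = (double)(sad / N);                     // MAD0
    out(j, c++) = (double)(sadm / N);                    // MAD1
    out(j, c++) = (double)sa;                            // IEMG
    out(j, c++) = maxav;                                 // MAXAV
    out(j, c++) = zc;                                    // ZC
    out(j, c++) = (double)ser;                           // AVSER
    out(j, c++) = (double)ssq;                           // AVSSR
    out(j, c++) = cov;                                   // COV
    out(j, c++) = (double)(wl / (N - 1));                // DAMV
    out(j, c++) = q75 - q25;                             // IQR
    out(j, c++) = (double)(ssq / N);                     // MVSR
    out(j, c++) = minav;                                 // MINAV
  }
  return out;
}
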