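#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Streaming generator of a moving-average filtered uniform series.
// Raw samples are U(-0.5, 0.5); the first M-1 raws are warm-up so every
// output sample is a full trailing mean of M raws (no edge effects).
struct FilteredStream {
  int M;
  std::vector<double> buf; // circular buffer of raw samples
  int pos;
  double sum;
  explicit FilteredStream(int M_) : M(M_), buf(M_, 0.0), pos(0), sum(0.0) {
    for (int i = 0; i < M - 1; ++i) push(unif_rand() - 0.5);
  }
  void push(double v) {
    sum += v - buf[pos];
    buf[pos] = v;
    pos = (pos + 1) % M;
  }
  double next() {
    push(unif_rand() - 0.5);
    return sum / M;
  }
};

static inline double pearson(double sx, double sy, double sxx, double syy,
                             double sxy, int n) {
  double vx = sxx - sx * sx / n;
  double vy = syy - sy * sy / n;
  double cxy = sxy - sx * sy / n;
  if (vx <= 0.0 || vy <= 0.0) return NA_REAL;
  return cxy / std::sqrt(vx * vy);
}

//' @noRd
// [[Rcpp::export(name = "cpp_pair_abs_corr")]]
NumericVector cpp_pair_abs_corr(int n_pairs, int n_samples, int M) {
  if (n_pairs < 1 || n_samples < 2 || M < 1) stop("invalid arguments");
  NumericVector out(n_pairs);
  for (int p = 0; p < n_pairs; ++p) {
    FilteredStream fx(M), fy(M);
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int t = 0; t < n_samples; ++t) {
      double x = fx.next(), y = fy.next();
      sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
    }
    out[p] = std::abs(pearson(sx, sy, sxx, syy, sxy, n_samples));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_triple_abs_corr")]]
NumericMatrix cpp_triple_abs_corr(int n_triples, int n_samples, int M) {
  if (n_triples < 1 || n_samples < 2 || M < 1) stop("invalid arguments");
  // columns: |r12|, |r23|, |r13|
  NumericMatrix out(n_triples, 3);
  for (int p = 0; p < n_triples; ++p) {
    FilteredStream f1(M), f2(M), f3(M);
    double s1 = 0, s2 = 0, s3 = 0;
    double s11 = 0, s22 = 0, s33 = 0, s12 = 0, s23 = 0, s13 = 0;
    for (int t = 0; t < n_samples; ++t) {
      double x = f1.next(), y = f2.next(), z = f3.next();
      s1 += x; s2 += y; s3 += z;
      s11 += x * x; s22 += y * y; s33 += z * z;
      s12 += x * y; s23 += y * z; s13 += x * z;
    }
    out(p, 0) = std::abs(pearson(s1, s2, s11, s22, s12, n_samples));
    out(p, 1) = std::abs(pearson(s2, s3, s22, s33, s23, n_samples));
    out(p, 2) = std::abs(pearson(s1, s3, s11, s33, s13, n_samples));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_white_abs_corr_prefix")]]
NumericMatrix cpp_white_abs_corr_prefix(int n_pairs, IntegerVector lengths) {
  // |r| of white-noise pairs evaluated on nested prefixes of one stream:
  // common random numbers across candidate lengths, so the edge-density
  // curve family is smooth in N for the effective-length fit.
  int K = lengths.size();
  if (n_pairs < 1 || K < 1) stop("invalid arguments");
  for (int k = 0; k < K; ++k) {
    if (lengths[k] < 2) stop("all lengths must be >= 2");
    if (k > 0 && lengths[k] <= lengths[k - 1]) stop("lengths must be strictly increasing");
  }
  int n_max = lengths[K - 1];
  NumericMatrix out(n_pairs, K);
  for (int p = 0; p < n_pairs; ++p) {
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    int k = 0;
    for (int t = 1; t <= n_max; ++t) {
      double x = unif_rand() - 0.5, y = unif_rand() - 0.5;
      sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
      if (k < K && t == lengths[k]) {
        out(p, k) = std::abs(pearson(sx, sy, sxx, syy, sxy, t));
        ++k;
      }
    }
  }
  return out;
}
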