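#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Medcouple: median of the kernel h(x_i, x_j) = ((x_j-m)-(m-x_i))/(x_j-x_i)
// over all pairs x_i <= m <= x_j, with the standard tie kernel for pairs of
// observations equal to the median m. Computed by the O(n log n) selection
// algorithm on the implicitly sorted kernel matrix (rows/columns
// non-increasing), selecting the two central order statistics and averaging
// them, which reproduces the naive full-enumeration median exactly.

namespace {

inline int signum(long v) { return (v > 0) - (v < 0); }

struct MCKernel {
  const std::vector<double>& zp;  // x - m for x >= m, decreasing (>= 0)
  const std::vector<double>& zm;  // x - m for x <= m, decreasing (<= 0)
  long p;
  double operator()(long i, long j) const {
    double a = zp[i], b = zm[j];
    if (a == b) return (double)signum(p - 1 - i - j);
    return (a + b) / (a - b);
  }
};

// lower weighted median of values with positive integer weights
double weighted_median(std::vector<double> a, std::vector<long> w) {
  std::vector<size_t> idx(a.size());
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end(),
            [&](size_t l, size_t r) { return a[l] < a[r]; });
  double wtot = 0;
  for (long wi : w) wtot += wi;
  double cum = 0;
  for (size_t t : idx) {
    cum += w[t];
    if (cum >= wtot / 2.0) return a[t];
  }
  return a[idx.back()];
}

// k-th largest (0-based) among all p*q kernel values
double kth_largest(const MCKernel& h, long p, long q, long k) {
  std::vector<long> L(p, 0), R(p, q - 1);
  long Ltot = 0, Rtot = p * q;
  int it = 0;
  while (Rtot - Ltot > p) {
    if (++it > 300) break;  // safety net: enumerate what remains
    std::vector<double> A;
    std::vector<long> W;
    A.reserve(p); W.reserve(p);
    for (long i = 0; i < p; ++i) {
      if (L[i] <= R[i]) {
        A.push_back(h(i, (L[i] + R[i]) / 2));
        W.push_back(R[i] - L[i] + 1);
      }
    }
    double am = weighted_median(std::move(A), std::move(W));
    // tentative boundaries: P[i] = greatest j with h(i,j) > am,
    //                       Q[i] = least j with h(i,j) < am
    std::vector<long> P(p), Q(p);
    {
      long j = 0;
      for (long i = p - 1; i >= 0; --i) {
        while (j < q && h(i, j) > am) ++j;
        P[i] = j - 1;
      }
    }
    {
      long j = q - 1;
      for (long i = 0; i < p; ++i) {
        while (j >= 0 && h(i, j) < am) --j;
        Q[i] = j + 1;
      }
    }
    long sumP = p, sumQ = 0;
    for (long i = 0; i < p; ++i) { sumP += P[i]; sumQ += Q[i]; }
    if (k <= sumP - 1) {
      R = P; Rtot = sumP;
    } else if (k > sumQ - 1) {
      L = Q; Ltot = sumQ;
    } else {
      return am;
    }
  }
  std::vector<double> cand;
  cand.reserve(Rtot - Ltot);
  for (long i = 0; i < p; ++i)
    for (long j = L[i]; j <= R[i]; ++j) cand.push_back(h(i, j));
  long target = k - Ltot;  // index in descending order
  std::nth_element(cand.begin(), cand.begin() + target, cand.end(),
                   std::greater<double>());
  return cand[target];
}

double mc_sorted_desc(const std::vector<double>& x) {
  const long n = (long)x.size();
  double m = (x[(n - 1) / 2] + x[n / 2]) / 2.0;
  std::vector<double> zp, zm;
  for (double v : x) {
    if (v >= m) zp.push_back(v - m);
    if (v <= m) zm.push_back(v - m);
  }
  long p = (long)zp.size(), q = (long)zm.size();
  MCKernel h{zp, zm, p};
  long t = p * q;
  long k1 = (t - 1) / 2, k2 = t / 2;
  double v1 = kth_largest(h, p, q, k1);
  if (k1 == k2) return v1;
  return (v1 + kth_largest(h, p, q, k2)) / 2.0;
}

} // namespace

// [[Rcpp::export(name = ".mc_cpp")]]
double mc_cpp(NumericVector x) {
  const R_xlen_t n = x.size();
  if (n < 3) return NA_REAL;
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end(), std::greater<double>());
  if (xs.front() == xs.back()) return NA_REAL;
  return mc_sorted_desc(xs);
}

// Percentile-bootstrap replicates of the medcouple. Uses R's RNG, so the
// caller's set.seed() makes the draw deterministic.
// [[Rcpp::export(name = ".mc_boot_cpp")]]
NumericVector mc_boot_cpp(NumericVector x, int n_boot) {
  const R_xlen_t n = x.size();
  NumericVector out(n_boot);
  std::vector<double> xb(n);
  for (int b = 0; b < n_boot; ++b) {
    for (R_xlen_t i = 0; i < n; ++i) {
      R_xlen_t j = (R_xlen_t)(unif_rand() * n);
      if (j == n) j = n - 1; // unif_rand() can get arbitrarily close to 1
      xb[i] = x[j];
    }
    std::sort(xb.begin(), xb.end(), std::greater<double>());
    out[b] = (xb.front() == xb.back()) ? NA_REAL : mc_sorted_desc(xb);
  }
  return out;
}
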