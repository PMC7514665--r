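#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// first index with tols[idx] >= d (tols sorted ascending)
static inline int lower_idx(const double *tols, int nt, double d) {
  int lo = 0, hi = nt;
  while (lo < hi) {
    int mid = (lo + hi) >> 1;
    if (tols[mid] < d)
      lo = mid + 1;
    else
      hi = mid;
  }
  return lo;
}

// Richman-Moorman pair counting: templates i = 1..N-m for BOTH lengths m and
// m+1, self-matches excluded, Chebyshev distance. For a sorted ascending
// tolerance vector the counts for every tolerance are accumulated in one pass
// over the pairs via a histogram + prefix sum, so a whole (r x SD-mode)
// tolerance grid costs the same O(N^2) sweep as a single tolerance. Pairs
// whose distance exceeds the largest tolerance are skipped as early as
// possible.
static void count_pairs(const double *x, int n, int m, const double *tols,
                        int nt, double *A, double *B, double *hb,
                        double *ha) {
  const double tmax = tols[nt - 1];
  std::fill(hb, hb + nt, 0.0);
  std::fill(ha, ha + nt, 0.0);
  const int M = n - m; // number of templates
  for (int i = 0; i < M - 1; ++i) {
    const double *xi = x + i;
    for (int j = i + 1; j < M; ++j) {
      const double *xj = x + j;
      double dm = std::fabs(xi[0] - xj[0]);
      if (dm > tmax)
        continue;
      bool out = false;
      for (int k = 1; k < m; ++k) {
        double d = std::fabs(xi[k] - xj[k]);
        if (d > dm) {
          dm = d;
          if (dm > tmax) {
            out = true;
            break;
          }
        }
      }
      if (out)
        continue;
      hb[lower_idx(tols, nt, dm)] += 1.0;
      double d1 = std::fabs(xi[m] - xj[m]);
      double dm1 = d1 > dm ? d1 : dm;
      if (dm1 <= tmax)
        ha[lower_idx(tols, nt, dm1)] += 1.0;
    }
  }
  double cb = 0.0, ca = 0.0;
  for (int t = 0; t < nt; ++t) {
    cb += hb[t];
    ca += ha[t];
    B[t] = cb;
    A[t] = ca;
  }
}

// [[Rcpp::export(name = ".sampenPairCounts")]]
List sampen_pair_counts(NumericVector x, int m, NumericVector tols) {
  if (x.size() <= m + 1)
    stop("window too short: need length > m + 1");
  const int nt = tols.size();
  NumericVector A(nt), B(nt);
  std::vector<double> hb(nt), ha(nt);
  count_pairs(REAL(x), x.size(), m, REAL(tols), nt, REAL(A), REAL(B),
              hb.data(), ha.data());
  return List::create(_["A"] = A, _["B"] = B);
}

// Counts for every moving window (start offsets 0, step, 2*step, ...;
// trailing partial window dropped) and every tolerance. Returns nwin x ntol
// matrices.
// [[Rcpp::export(name = ".movingSampenCounts")]]
List moving_sampen_counts(NumericVector x, int N, int step, int m,
                          NumericVector tols) {
  const int n = x.size();
  if (N > n)
    stop("signal shorter than one window");
  if (N <= m + 1)
    stop("window too short: need N > m + 1");
  if (step < 1)
    stop("step must be >= 1");
  const int nt = tols.size();
  const int nwin = (n - N) / step + 1;
  NumericMatrix A(nwin, nt), B(nwin, nt);
  std::vector<double> a(nt), b(nt), hb(nt), ha(nt);
  for (int w = 0; w < nwin; ++w) {
    count_pairs(REAL(x) + static_cast<R_xlen_t>(w) * step, N, m, REAL(tols),
                nt, a.data(), b.data(), hb.data(), ha.data());
    for (int t = 0; t < nt; ++t) {
      A(w, t) = a[t];
      B(w, t) = b[t];
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Per-lag Pearson correlation (or mean-removed covariance when
// normalized = false) between x and y for integer lags -L..L. Lag k pairs
// x[i] with y[i-k], i.e. positive lag means x is delayed relative to y.
// Means and variances are recomputed on each lag's overlap.
// [[Rcpp::export(name = ".crossPearson")]]
NumericVector cross_pearson(NumericVector x, NumericVector y, int L,
                            bool normalized) {
  const int n = x.size();
  if (y.size() != n)
    stop("x and y must have equal length");
  const double *px = REAL(x), *py = REAL(y);
  NumericVector out(2 * L + 1);
  for (int k = -L; k <= L; ++k) {
    const int i0 = std::max(0, k);
    const int i1 = n - 1 + std::min(0, k);
    const int len = i1 - i0 + 1;
    if (len < 3) {
      out[k + L] = NA_REAL;
      continue;
    }
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int i = i0; i <= i1; ++i) {
      const double xi = px[i], yi = py[i - k];
      sx += xi;
      sy += yi;
      sxx += xi * xi;
      syy += yi * yi;
      sxy += xi * yi;
    }
    const double vx = sxx - sx * sx / len;
    const double vy = syy - sy * sy / len;
    const double cv = sxy - sx * sy / len;
    if (normalized)
      out[k + L] = (vx > 0.0 && vy > 0.0) ? cv / std::sqrt(vx * vy) : NA_REAL;
    else
      out[k + L] = cv / len;
  }
  return out;
}
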