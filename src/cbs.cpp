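#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Circular binary segmentation split scan.
//
// For an arc of length k with centred-series sum D, the between-group sum of
// squares is B = n * D^2 / (k * (n - k)) and the two-sample t statistic
// satisfies t^2 = B * (n - 2) / (TSS - B), which is strictly increasing in B
// (TSS, the total centred sum of squares, is fixed).  Maximising t^2 is
// therefore maximising g = D^2 / (k * (n - k)), and because TSS is invariant
// under permutation of the segment, a permuted segment exceeds the observed
// statistic iff some admissible arc has D^2 >= g_obs * k * (n - k).  That
// reduces the permutation scan to one subtraction, multiply and compare per
// arc, with a precomputed per-length threshold.
//
// Admissible splits keep every resulting linear piece at least mw long:
// arc length k in [mw, n - mw]; i == 0 or i >= mw; j == n or j <= n - mw;
// and not (i == 0 and j == n).  Ties in the maximum go to the smallest
// (i, j) in lexicographic order.

namespace {

struct ScanResult {
  double g;        // max D^2 / (k (n - k)) over admissible arcs
  int i, j;        // 0-based boundaries of the best arc [i, j)
  double npairs;   // number of admissible arcs
};

// Prefix sums of the centred series into Sc[0..n].
inline void centred_prefix(const double* x, int n, std::vector<double>& Sc) {
  double tot = 0.0;
  for (int a = 0; a < n; ++a) tot += x[a];
  const double mu = tot / n;
  Sc[0] = 0.0;
  for (int a = 0; a < n; ++a) Sc[a + 1] = Sc[a] + (x[a] - mu);
}

ScanResult scan_best(const std::vector<double>& Sc, int n, int mw) {
  ScanResult best = {0.0, -1, -1, 0.0};
  if (n < 2 * mw) return best;
  std::vector<double> invkk(n);
  for (int k = mw; k <= n - mw; ++k) invkk[k] = 1.0 / ((double)k * (n - k));
  double npairs = 0.0;
  for (int i = 0; i + mw <= n; ++i) {
    if (i != 0 && i < mw) continue;
    const double si = Sc[i];
    // interior j, then the j == n suffix arc (skipping the full circle)
    const int jhi = n - mw;
    for (int j = i + mw; j <= jhi; ++j) {
      const double d = Sc[j] - si;
      const double g = d * d * invkk[j - i];
      npairs += 1.0;
      if (g > best.g) { best.g = g; best.i = i; best.j = j; }
    }
    if (i >= mw && n - i >= mw) {  // j == n, i > 0
      const double d = Sc[n] - si;
      const double g = d * d * invkk[n - i];
      npairs += 1.0;
      if (g > best.g) { best.g = g; best.i = i; best.j = n; }
    }
  }
  best.npairs = npairs;
  return best;
}

// Does any admissible arc of the permuted segment reach g_obs?
bool scan_exceeds(const std::vector<double>& Sc, int n, int mw,
                  const std::vector<double>& thr) {
  const double* a = Sc.data();
  for (int k = mw; k <= n - mw; ++k) {
    const double t = thr[k];
    // i = 0 (prefix arc, j = k < n since k <= n - mw)
    double d = a[k];
    if (d * d >= t) return true;
    // i = n - k (suffix arc, j = n) when i >= mw
    if (n - k >= mw) {
      d = a[n] - a[n - k];
      if (d * d >= t) return true;
    }
    // interior i in [mw, n - k - mw]
    const int ihi = n - k - mw;
    for (int i = mw; i <= ihi; ++i) {
      d = a[i + k] - a[i];
      if (d * d >= t) return true;
    }
  }
  return false;
}

inline double g_to_t2(double g, int n, double tss, double eps) {
  const double B = n * g;
  const double denom = tss - B;
  if (denom <= eps)
    return std::numeric_limits<double>::infinity();
  return B * (double)(n - 2) / denom;
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List cpp_cbs_scan(NumericVector x, int min_width) {
  const int n = (int)x.size();
  std::vector<double> Sc(n + 1);
  double tss = 0.0;
  if (n >= 1) {
    centred_prefix(x.begin(), n, Sc);
    double tot = 0.0;
    for (int a = 0; a < n; ++a) tot += x[a];
    const double mu = tot / n;
    for (int a = 0; a < n; ++a) tss += (x[a] - mu) * (x[a] - mu);
  }
  ScanResult r = (n >= 1) ? scan_best(Sc, n, min_width)
                          : ScanResult{0.0, -1, -1, 0.0};
  const double eps = 1e-12 * std::max(1.0, tss);
  const double t2 = (r.i < 0 || r.g <= eps / std::max(1, n))
                        ? 0.0 : g_to_t2(r.g, n, tss, eps);
  return List::create(_["t2"] = t2, _["i"] = r.i, _["j"] = r.j,
                      _["npairs"] = r.npairs);
}

// [[Rcpp::export]]
List cpp_cbs_decide(NumericVector x, int min_width, double alpha, int n_perm,
                    bool fast_accept, double fast_margin) {
  const int n = (int)x.size();
  std::vector<double> Sc(n + 1);
  double tot = 0.0, tss = 0.0;
  for (int a = 0; a < n; ++a) tot += x[a];
  const double mu = (n > 0) ? tot / n : 0.0;
  for (int a = 0; a < n; ++a) tss += (x[a] - mu) * (x[a] - mu);
  const double eps = 1e-12 * std::max(1.0, tss);
  List no_split = List::create(_["split"] = false, _["i"] = -1, _["j"] = -1,
                               _["t2"] = 0.0, _["p"] = 1.0,
                               _["method"] = "none");
  if (n < 2 * min_width || tss <= eps) return no_split;
  centred_prefix(x.begin(), n, Sc);
  ScanResult obs = scan_best(Sc, n, min_width);
  if (obs.i < 0 || obs.g * n <= eps) return no_split;
  const double t2 = g_to_t2(obs.g, n, tss, eps);
  if (fast_accept && n >= 30 && std::isfinite(t2)) {
    const double t = std::sqrt(t2);
    const double pbon = obs.npairs * 2.0 * R::pt(-t, (double)(n - 2), 1, 0);
    if (pbon < alpha * fast_margin) {
      return List::create(_["split"] = true, _["i"] = obs.i, _["j"] = obs.j,
                          _["t2"] = t2, _["p"] = pbon,
                          _["method"] = "analytic");
    }
  }
  // permutation test with curtailed sampling: once the exceedance count
  // reaches ceil(alpha * n_perm) the split can no longer reach p < alpha
  int reject_at = (int)std::ceil(alpha * n_perm - 1e-9);
  if (reject_at < 1) reject_at = 1;
  std::vector<double> thr(n + 1, 0.0);
  for (int k = min_width; k <= n - min_width; ++k)
    thr[k] = obs.g * (double)k * (double)(n - k);
  std::vector<double> buf(x.begin(), x.end());
  std::vector<double> Sp(n + 1);
  int count = 0, done = 0;
  for (int e = 1; e <= n_perm; ++e) {
    for (int a = n - 1; a > 0; --a) {  // Fisher-Yates on R's RNG stream
      int b = (int)(unif_rand() * (a + 1));
      if (b > a) b = a;
      std::swap(buf[a], buf[b]);
    }
    centred_prefix(buf.data(), n, Sp);
    done = e;
    if (scan_exceeds(Sp, n, min_width, thr)) {
      ++count;
      if (count >= reject_at) break;
    }
  }
  const bool split = count < reject_at;
  return List::create(_["split"] = split, _["i"] = obs.i, _["j"] = obs.j,
                      _["t2"] = t2,
                      _["p"] = (double)count / (double)done,
                      _["method"] = "permutation");
}
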