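#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Box-assisted template matching for ApEn / C-ApEn.
//
// Targets are sorted by first-coordinate value; for a template starting at
// i only starts j with |first coords| <= r can match, so a two-pointer sweep
// restricts the inner loop to that window. Later coordinates are
// pre-gathered into arrays laid out in sorted order (sequential scans), and
// out-of-range starts are padded with NaN so every comparison against them
// fails without an explicit validity branch. Matching follows the classical
// definition: Chebyshev distance, strict "<= r"; ApEn includes the
// self-match, C-ApEn has none to include.

namespace {

struct SortedTargets {
  std::vector<int> ord;                       // target starts, sorted by value
  std::vector<std::vector<double> > coord;    // coord[k][q] = x[ord[q] + k] or NaN
};

SortedTargets sort_targets(const NumericVector& x, int m) {
  const int N = x.size();
  SortedTargets st;
  st.ord.resize(N);
  std::iota(st.ord.begin(), st.ord.end(), 0);
  std::sort(st.ord.begin(), st.ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  st.coord.assign(m + 1,
      std::vector<double>(N, std::numeric_limits<double>::quiet_NaN()));
  for (int q = 0; q < N; ++q) {
    const int j = st.ord[q];
    for (int k = 0; k <= m && j + k < N; ++k) st.coord[k][q] = x[j + k];
  }
  return st;
}

// Per-template match counts of u-templates against the sorted targets.
// cm[i] counts length-m matches for i in 0..nm-1; cm1[i] length-(m+1)
// matches for i in 0..nm1-1.
void count_matches(const NumericVector& u, const SortedTargets& st,
                   int m, double r, int nm, int nm1,
                   std::vector<int>& cm, std::vector<int>& cm1) {
  const int N = u.size();
  std::vector<int> ou(N);
  std::iota(ou.begin(), ou.end(), 0);
  std::sort(ou.begin(), ou.end(), [&](int a, int b) { return u[a] < u[b]; });

  const double* t0 = st.coord[0].data();
  int lo = 0, hi = 0;
  for (int pos = 0; pos < N; ++pos) {
    const int i = ou[pos];
    const double ui = u[i];
    while (lo < N && t0[lo] < ui - r) ++lo;
    while (hi < N && t0[hi] <= ui + r) ++hi;
    if (i >= nm) continue;
    const bool i_m1 = i < nm1;
    int cnt = 0, cnt1 = 0;
    if (m == 2) {          // branchless fast path for the default setting
      const double* c1 = st.coord[1].data();
      const double* c2 = st.coord[2].data();
      const double ui1 = u[i + 1];
      const double ui2 = i_m1 ? u[i + 2] : 0.0;
      for (int q = lo; q < hi; ++q) {
        const int a = std::abs(ui1 - c1[q]) <= r;
        cnt += a;
        cnt1 += a & (int)(std::abs(ui2 - c2[q]) <= r);
      }
    } else {
      for (int q = lo; q < hi; ++q) {
        int good = 1;
        for (int k = 1; k < m; ++k)
          good &= (int)(std::abs(u[i + k] - st.coord[k][q]) <= r);
        cnt += good;
        if (good && i_m1 &&
            std::abs(u[i + m] - st.coord[m][q]) <= r) ++cnt1;
      }
    }
    cm[i] = cnt;
    if (i_m1) cm1[i] = cnt1;
  }
}

}  // namespace

// [[Rcpp::export]]
double apen_cpp(NumericVector u, int m, double r) {
  const int N = u.size();
  const int nm = N - m + 1;   // number of length-m templates
  const int nm1 = N - m;      // number of length-(m+1) templates
  if (m < 1) stop("m must be >= 1");
  if (nm1 < 1) stop("series too short for the requested embedding dimension");
  // Self-comparison is symmetric, so each unordered pair is examined once
  // and credited to both templates; self-matches are added up front.
  std::vector<int> cm(N, 0), cm1(N, 0);
  for (int i = 0; i < nm; ++i) cm[i] = 1;
  for (int i = 0; i < nm1; ++i) cm1[i] = 1;
  SortedTargets st = sort_targets(u, m);
  // u padded with NaN so coordinates of invalid template starts poison the
  // comparison instead of reading out of bounds
  std::vector<double> up(N + m + 1,
                         std::numeric_limits<double>::quiet_NaN());
  std::copy(u.begin(), u.end(), up.begin());

  const double* c0 = st.coord[0].data();
  int hi = 0;
  for (int pos = 0; pos < N; ++pos) {
    const int i = st.ord[pos];
    const double ui = c0[pos];
    while (hi < N && c0[hi] <= ui + r) ++hi;
    int cnt = 0, cnt1 = 0;
    if (m == 2) {
      const double* c1 = st.coord[1].data();
      const double* c2 = st.coord[2].data();
      const double ui1 = up[i + 1];
      const double ui2 = up[i + 2];
      const int* op = st.ord.data();
      for (int q = pos + 1; q < hi; ++q) {
        const int a = std::abs(ui1 - c1[q]) <= r;
        const int b = a & (int)(std::abs(ui2 - c2[q]) <= r);
        cnt += a;
        cnt1 += b;
        cm[op[q]] += a;
        cm1[op[q]] += b;
      }
    } else {
      for (int q = pos + 1; q < hi; ++q) {
        int good = 1;
        for (int k = 1; k < m; ++k)
          good &= (int)(std::abs(up[i + k] - st.coord[k][q]) <= r);
        if (!good) continue;
        ++cnt;
        ++cm[st.ord[q]];
        if (std::abs(up[i + m] - st.coord[m][q]) <= r) {
          ++cnt1;
          ++cm1[st.ord[q]];
        }
      }
    }
    cm[i] += cnt;
    cm1[i] += cnt1;
  }

  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) phim += std::log((double)cm[i] / nm);
  phim /= nm;
  for (int i = 0; i < nm1; ++i) phim1 += std::log((double)cm1[i] / nm1);
  phim1 /= nm1;
  return phim - phim1;
}

// [[Rcpp::export]]
List capen_cpp(NumericVector u, NumericVector v, int m, double r) {
  const int N = u.size();
  if (v.size() != N) stop("series lengths differ");
  const int nm = N - m + 1;
  const int nm1 = N - m;
  if (m < 1) stop("m must be >= 1");
  if (nm1 < 1) stop("series too short for the requested embedding dimension");
  std::vector<int> cm(nm, 0), cm1(nm1, 0);
  SortedTargets st = sort_targets(v, m);
  count_matches(u, st, m, r, nm, nm1, cm, cm1);

  // zero-match templates are excluded from each level's average and counted
  int zm = 0, zm1 = 0;
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) {
    if (cm[i] == 0) { ++zm; continue; }
    phim += std::log((double)cm[i] / nm);
  }
  for (int i = 0; i < nm1; ++i) {
    if (cm1[i] == 0) { ++zm1; continue; }
    phim1 += std::log((double)cm1[i] / nm1);
  }
  double value = NA_REAL;
  if (zm < nm && zm1 < nm1) {
    phim /= (nm - zm);
    phim1 /= (nm1 - zm1);
    value = phim - phim1;
  }
  return List::create(_["value"] = value,
                      _["n_templates_m"] = nm, _["n_zero_m"] = zm,
                      _["n_templates_m1"] = nm1, _["n_zero_m1"] = zm1);
}
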