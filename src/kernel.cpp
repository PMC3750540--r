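#include <Rcpp.h>
using namespace Rcpp;

// Area distances between the Kaplan-Meier curves of genotype-combination
// groups, computed in one pass over the cohort.
//
// Inputs must be sorted by ascending time with events before censorings at
// tied times (the standard KM tie convention).  `code` holds the group code
// of each sample (0..8 for a marker pair); samples excluded from the family
// must already be removed by the caller.
//
// The curves are right-continuous step functions on the shared grid
// {0, observed times...}; the area between two curves is accumulated
// lazily: a pair's running integral is flushed only when one of its two
// curves drops (at an event) and once more at the last follow-up time, so
// the work is O(events * groups) instead of O(samples * group pairs).
// Rectangle heights are taken at the left endpoint of each grid segment,
// which is exact for step curves.  Duplicate times yield zero-width
// segments and contribute nothing.
//
// Returns the symmetric distance matrix over the groups present (sorted by
// code), the group codes, and the group sizes.
// [[Rcpp::export(name = ".km_area_kernel")]]
List km_area_kernel(IntegerVector code, NumericVector ts, IntegerVector ev) {
  const int n = code.size();
  if (ts.size() != n || ev.size() != n)
    stop("code, ts and ev must have equal length");
  if (n == 0) stop("empty family");

  const int *pc = INTEGER(code);
  const double *pt = REAL(ts);
  const int *pe = INTEGER(ev);

  int cnt[9] = {0};
  for (int i = 0; i < n; ++i) {
    if (pc[i] < 0 || pc[i] > 8) stop("group codes must lie in 0..8");
    ++cnt[pc[i]];
  }
  int map[9];
  std::vector<int> codes;
  for (int c = 0; c < 9; ++c) {
    map[c] = -1;
    if (cnt[c] > 0) { map[c] = (int)codes.size(); codes.push_back(c); }
  }
  const int m = (int)codes.size();

  double curS[9], atrisk[9];
  double acc[81], lastT[81];   // row-major m x m, upper triangle used
  for (int j = 0; j < m; ++j) {
    curS[j] = 1.0;
    atrisk[j] = (double)cnt[codes[j]];
  }
  for (int j = 0; j < m * m; ++j) { acc[j] = 0.0; lastT[j] = 0.0; }

  double prev = 0.0;
  for (int i = 0; i < n; ++i) {
    const double t = pt[i];
    if (t < prev) stop("times must be sorted ascending");
    prev = t;
    const int g = map[pc[i]];
    if (pe[i] == 1) {
      const double sg = curS[g];
      for (int j = 0; j < m; ++j) {
        if (j == g) continue;
        const int idx = g < j ? g * m + j : j * m + g;
        acc[idx] += (t - lastT[idx]) * std::fabs(sg - curS[j]);
        lastT[idx] = t;
      }
      curS[g] = sg * (1.0 - 1.0 / atrisk[g]);
    }
    atrisk[g] -= 1.0;
  }
  const double tn = pt[n - 1];

  NumericMatrix D(m, m);
  for (int j = 0; j < m - 1; ++j) {
    for (int k = j + 1; k < m; ++k) {
      const int idx = j * m + k;
      const double d =
          acc[idx] + (tn - lastT[idx]) * std::fabs(curS[j] - curS[k]);
      D(j, k) = d;
      D(k, j) = d;
    }
  }

  NumericVector sizes(m);
  IntegerVector codes_out(m);
  for (int j = 0; j < m; ++j) {
    codes_out[j] = codes[j];
    sizes[j] = (double)cnt[codes[j]];
  }
  return List::create(_["D"] = D, _["codes"] = codes_out,
                      _["sizes"] = sizes);
}
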