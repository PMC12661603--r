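#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Total of the n-th smallest entry of each row of `d`, for n = 1..n_max.
// `d` is a cohort-by-sample distance matrix; result[n-1] is the coverage
// statistic at n (sum over cohort members of the distance to their n-th
// nearest sampled member).
// [[Rcpp::export(name = ".row_nsmallest_totals")]]
NumericVector row_nsmallest_totals(NumericMatrix d, int n_max) {
  const int nr = d.nrow(), nc = d.ncol();
  if (n_max < 1 || n_max > nc)
    stop("n_max must lie in 1..ncol(d)");
  NumericVector out(n_max);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = d(i, j);
    std::partial_sort(buf.begin(), buf.begin() + n_max, buf.end());
    for (int n = 0; n < n_max; ++n) out[n] += buf[n];
  }
  return out;
}

// Same statistic computed directly from a numeric feature matrix `x`
// (rows = cohort members) and 1-based sample row indices, avoiding the
// N-by-m distance matrix. Euclidean by default, Manhattan when `manhattan`.
// [[Rcpp::export(name = ".nn_totals_numeric")]]
NumericVector nn_totals_numeric(NumericMatrix x, IntegerVector sample,
                                int n_max, bool manhattan) {
  const int n = x.nrow(), p = x.ncol(), m = sample.size();
  if (n_max < 1 || n_max > m)
    stop("n_max must lie in 1..length(sample)");
  // sample rows copied row-major for cache-friendly inner loops
  std::vector<double> s(static_cast<size_t>(m) * p);
  for (int j = 0; j < m; ++j) {
    const int r = sample[j] - 1;
    if (r < 0 || r >= n) stop("sample index out of range");
    for (int f = 0; f < p; ++f) s[static_cast<size_t>(j) * p + f] = x(r, f);
  }
  NumericVector out(n_max);
  std::vector<double> row(p), buf(m);
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < p; ++f) row[f] = x(i, f);
    for (int j = 0; j < m; ++j) {
      const double* sj = &s[static_cast<size_t>(j) * p];
      double acc = 0.0;
      if (manhattan) {
        for (int f = 0; f < p; ++f) acc += std::abs(row[f] - sj[f]);
      } else {
        for (int f = 0; f < p; ++f) {
          const double d = row[f] - sj[f];
          acc += d * d;
        }
      }
      buf[j] = acc;
    }
    std::partial_sort(buf.begin(), buf.begin() + n_max, buf.end());
    if (manhattan) {
      for (int nn = 0; nn < n_max; ++nn) out[nn] += buf[nn];
    } else {
      for (int nn = 0; nn < n_max; ++nn) out[nn] += std::sqrt(buf[nn]);
    }
  }
  return out;
}
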