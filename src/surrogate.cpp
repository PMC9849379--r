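#include <Rcpp.h>
using namespace Rcpp;

// Modulation index from per-bin amplitude sums and fixed bin counts.
static double mi_from_sums(const std::vector<double>& sums,
                           const IntegerVector& counts, int n_bins) {
  double tot = 0.0;
  std::vector<double> means(n_bins);
  for (int j = 0; j < n_bins; ++j) {
    means[j] = counts[j] > 0 ? sums[j] / counts[j] : 0.0;
    tot += means[j];
  }
  if (tot <= 0.0) return 0.0;
  double d = 0.0;
  for (int j = 0; j < n_bins; ++j) {
    double p = means[j] / tot;
    if (p > 0.0) d += p * std::log(n_bins * p);
  }
  return d / std::log((double)n_bins);
}

// Surrogate coupling strengths for one low-frequency column under circular
// time shifts.  bins: per-sample phase-bin index (1-based) of the low
// column; amp: n x n_high amplitude envelopes; offsets: 0-based circular
// shifts, one per shuffle.  Returns an (n_shuffles x n_high) matrix of
// modulation indices computed with the amplitude series rotated against the
// fixed phase binning.
// [[Rcpp::export]]
NumericMatrix surr_strength_shift(IntegerVector bins, NumericMatrix amp,
                                  IntegerVector offsets, int n_bins) {
  const int n = bins.size();
  const int n_high = amp.ncol();
  const int n_sh = offsets.size();
  if (amp.nrow() != n) stop("bins and amp lengths differ");
  IntegerVector counts(n_bins);
  for (int t = 0; t < n; ++t) {
    int b = bins[t] - 1;
    if (b < 0 || b >= n_bins) stop("bin index out of range");
    counts[b]++;
  }
  NumericMatrix out(n_sh, n_high);
  std::vector<double> sums(n_bins);
  for (int r = 0; r < n_high; ++r) {
    const double* a = &amp(0, r);
    for (int s = 0; s < n_sh; ++s) {
      int off = offsets[s] % n;
      if (off < 0) off += n;
      std::fill(sums.begin(), sums.end(), 0.0);
      // amp index runs off..n-1 then 0..off-1 while bins run 0..n-1
      int t = 0;
      for (int u = off; u < n; ++u, ++t) sums[bins[t] - 1] += a[u];
      for (int u = 0; u < off; ++u, ++t) sums[bins[t] - 1] += a[u];
      out(s, r) = mi_from_sums(sums, counts, n_bins);
    }
  }
  return out;
}

// Same contract but with explicit permutations (n x n_shuffles, 1-based):
// shuffle s pairs amp[perm[t, s]] with phase bin bins[t].
// [[Rcpp::export]]
NumericMatrix surr_strength_perm(IntegerVector bins, NumericMatrix amp,
                                 IntegerMatrix perms, int n_bins) {
  const int n = bins.size();
  const int n_high = amp.ncol();
  const int n_sh = perms.ncol();
  if (amp.nrow() != n || perms.nrow() != n) stop("dimension mismatch");
  IntegerVector counts(n_bins);
  for (int t = 0; t < n; ++t) {
    int b = bins[t] - 1;
    if (b < 0 || b >= n_bins) stop("bin index out of range");
    counts[b]++;
  }
  NumericMatrix out(n_sh, n_high);
  std::vector<double> sums(n_bins);
  for (int r = 0; r < n_high; ++r) {
    const double* a = &amp(0, r);
    for (int s = 0; s < n_sh; ++s) {
      const int* pm = &perms(0, s);
      std::fill(sums.begin(), sums.end(), 0.0);
      for (int t = 0; t < n; ++t) sums[bins[t] - 1] += a[pm[t] - 1];
      out(s, r) = mi_from_sums(sums, counts, n_bins);
    }
  }
  return out;
}
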