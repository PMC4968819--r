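// Monte-Carlo sampler for the circular coverage model: R community reads,
// each independently on-target with probability alpha; on-target reads are
// arcs of length l with uniform real-valued start positions on a circle of
// circumference L.  B = number of maximal uncovered intervals; B = 0 when no
// read lands on the target (a null assembly has no gaps).
//
// Because all arcs share one length, the gap count equals the number of
// circularly consecutive start pairs whose spacing exceeds l (a spacing of
// exactly l touches and counts as covered).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

static int count_gaps(std::vector<double>& starts, double l, double L) {
  const int m = (int)starts.size();
  if (m == 0) return 0;
  if (l >= L) return 0;
  std::sort(starts.begin(), starts.end());
  int gaps = 0;
  for (int i = 0; i < m; ++i) {
    double next = (i + 1 < m) ? starts[i + 1] : starts[0] + L;
    if (next - starts[i] > l) ++gaps;
  }
  return gaps;
}

// [[Rcpp::export(name = ".gap_count_trials")]]
Rcpp::IntegerVector gap_count_trials(int R, double l, double L, double alpha,
                                     int trials) {
  if (R < 0) Rcpp::stop("R must be non-negative");
  if (trials < 1) Rcpp::stop("trials must be positive");
  Rcpp::IntegerVector out(trials);
  std::vector<double> starts;
  starts.reserve(R);
  for (int t = 0; t < trials; ++t) {
    starts.clear();
    for (int r = 0; r < R; ++r) {
      if (alpha >= 1.0 || R::unif_rand() < alpha)
        starts.push_back(R::unif_rand() * L);
    }
    out[t] = count_gaps(starts, l, L);
  }
  return out;
}

// Gap count for explicit start positions, already reduced to [0, L)
// (used to check rotation invariance).
// [[Rcpp::export(name = ".gap_count_starts")]]
int gap_count_starts(Rcpp::NumericVector start_pos, double l, double L) {
  std::vector<double> starts(start_pos.begin(), start_pos.end());
  for (double s : starts)
    if (s < 0 || s >= L) Rcpp::stop("start positions must lie in [0, L)");
  return count_gaps(starts, l, L);
}
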