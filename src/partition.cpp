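#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

std::vector<int> hungarian_min(const std::vector<double>& a, int n);

// Transfer distance between two 0-based label vectors: N minus the maximal
// total cluster overlap under an optimal one-to-one matching of clusters
// (overlap matrix zero-padded to square, maximised by minimising its negation).
static int transfer_distance_int(const int* p1, const int* p2, int n) {
  int k1 = 0, k2 = 0;
  for (int i = 0; i < n; ++i) {
    if (p1[i] + 1 > k1) k1 = p1[i] + 1;
    if (p2[i] + 1 > k2) k2 = p2[i] + 1;
  }
  int m = std::max(k1, k2);
  std::vector<double> cost(m * m, 0.0);
  for (int i = 0; i < n; ++i) cost[p1[i] * m + p2[i]] -= 1.0;
  std::vector<int> ans = hungarian_min(cost, m);
  double tot = 0.0;
  for (int i = 0; i < m; ++i) tot += cost[i * m + ans[i]];
  int max_overlap = (int)(-tot + 0.5);
  return n - max_overlap;
}

// [[Rcpp::export]]
int transfer_distance_cpp(IntegerVector p1, IntegerVector p2) {
  return transfer_distance_int(INTEGER(p1), INTEGER(p2), p1.size());
}

// Sum of transfer distances from one candidate to every row of `samples`
// (S x N matrix of 0-based labels). Integer-exact.
static long long total_distance(const std::vector<int>& cand,
                                const IntegerMatrix& samples) {
  int S = samples.nrow(), n = samples.ncol();
  std::vector<int> row(n);
  long long tot = 0;
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < n; ++j) row[j] = samples(s, j);
    tot += transfer_distance_int(cand.data(), row.data(), n);
  }
  return tot;
}

// [[Rcpp::export]]
double mean_distance_cpp(IntegerVector candidate, IntegerMatrix samples) {
  std::vector<int> cand(candidate.begin(), candidate.end());
  return (double)total_distance(cand, samples) / samples.nrow();
}

// Index (1-based) of the sample with the smallest summed transfer distance
// to all samples; ties broken by lowest index.
// [[Rcpp::export]]
int best_sample_cpp(IntegerMatrix samples) {
  int S = samples.nrow(), n = samples.ncol();
  std::vector<long long> tot(S, 0);
  std::vector<int> a(n), b(n);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < n; ++j) a[j] = samples(s, j);
    for (int t = s + 1; t < S; ++t) {
      for (int j = 0; j < n; ++j) b[j] = samples(t, j);
      int d = transfer_distance_int(a.data(), b.data(), n);
      tot[s] += d;
      tot[t] += d;
    }
  }
  int best = 0;
  for (int s = 1; s < S; ++s) if (tot[s] < tot[best]) best = s;
  return best + 1;
}

// Relabel to consecutive 0-based labels in order of first appearance.
static int compact_labels(std::vector<int>& x) {
  std::vector<int> map(x.size(), -1);
  int next = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    if (map[x[i]] < 0) map[x[i]] = next++;
    x[i] = map[x[i]];
  }
  return next;
}

// Greedy median-partition search: cycle over items in ascending order,
// move each to the strictly best-improving target cluster (existing or new;
// lowest id wins ties); stop when a full cycle accepts no move. The summed
// distance is integer-valued, so strict decrease is an exact comparison.
// [[Rcpp::export]]
List median_partition_cpp(IntegerMatrix samples, IntegerVector init) {
  int n = samples.ncol();
  std::vector<int> cur(init.begin(), init.end());
  int K = compact_labels(cur);
  long long cur_td = total_distance(cur, samples);
  std::vector<double> trace;
  trace.push_back((double)cur_td / samples.nrow());
  bool improved = true;
  while (improved) {
    improved = false;
    Rcpp::checkUserInterrupt();
    for (int i = 0; i < n; ++i) {
      int a = cur[i];
      long long best_td = cur_td;
      int best_t = -1;
      for (int t = 0; t <= K; ++t) {
        if (t == a) continue;
        cur[i] = t;
        long long d = total_distance(cur, samples);
        if (d < best_td) { best_td = d; best_t = t; }
      }
      cur[i] = a;
      if (best_t >= 0) {
        cur[i] = best_t;
        cur_td = best_td;
        K = compact_labels(cur);
        improved = true;
        trace.push_back((double)cur_td / samples.nrow());
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cur[i] + 1;
  return List::create(_["assignments"] = out,
                      _["mean_distance"] = (double)cur_td / samples.nrow(),
                      _["trace"] = trace);
}
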