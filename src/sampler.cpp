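#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for the Dirichlet process mixture of independent
// categorical distributions. Component parameters are integrated out, so the
// state is just cluster sizes plus per-cluster per-dimension response tallies.
// All randomness comes from R's RNG (Rcpp attributes install an RNGScope),
// so set.seed() on the R side makes chains fully reproducible.

struct State {
  int N, D, sumV;
  std::vector<int> V, off;          // categories per dimension, count offsets
  std::vector<int> assign;          // current table per item, -1 = unseated
  std::vector<int> size;            // per-cluster item counts
  std::vector<std::vector<int>> cnt; // per-cluster response tallies (len sumV)

  State(int N_, const std::vector<int>& V_)
      : N(N_), D((int)V_.size()), V(V_), assign(N_, -1) {
    off.resize(D);
    sumV = 0;
    for (int d = 0; d < D; ++d) { off[d] = sumV; sumV += V[d]; }
  }
  int K() const { return (int)size.size(); }

  void add(int i, int k, const int* x) {
    if (k == K()) { size.push_back(0); cnt.push_back(std::vector<int>(sumV, 0)); }
    assign[i] = k;
    size[k] += 1;
    for (int d = 0; d < D; ++d) cnt[k][off[d] + x[i * D + d]] += 1;
  }
  void remove(int i, const int* x) {
    int k = assign[i];
    assign[i] = -1;
    size[k] -= 1;
    for (int d = 0; d < D; ++d) cnt[k][off[d] + x[i * D + d]] -= 1;
    if (size[k] == 0) {  // delete the emptied cluster, compact ids above it
      size.erase(size.begin() + k);
      cnt.erase(cnt.begin() + k);
      for (int j = 0; j < N; ++j) if (assign[j] > k) assign[j] -= 1;
    }
  }
};

// log posterior-predictive of item i's responses under cluster k:
// sum_d log (n_{k,d,o_d} + beta) - log (n_k + V_d * beta)
static double log_pred(const State& st, int k, int i, const int* x, double beta) {
  double lp = 0.0;
  const std::vector<int>& c = st.cnt[k];
  double nk = (double)st.size[k];
  for (int d = 0; d < st.D; ++d)
    lp += std::log(c[st.off[d] + x[i * st.D + d]] + beta) -
          std::log(nk + st.V[d] * beta);
  return lp;
}

// Seat one currently-unseated item: weight n_k * F_k for existing tables,
// alpha * F_new for a new one (the common 1/(N-1+alpha) cancels).
// prior-only mode drops the likelihood factors (pure CRP).
static void seat_item(State& st, int i, const int* x,
                      double alpha, double beta, bool use_lik, double log_fnew) {
  int K = st.K();
  std::vector<double> lw(K + 1);
  for (int k = 0; k < K; ++k) {
    lw[k] = std::log((double)st.size[k]);
    if (use_lik) lw[k] += log_pred(st, k, i, x, beta);
  }
  lw[K] = std::log(alpha);
  if (use_lik) lw[K] += log_fnew;
  double mx = lw[0];
  for (int k = 1; k <= K; ++k) if (lw[k] > mx) mx = lw[k];
  double tot = 0.0;
  for (int k = 0; k <= K; ++k) { lw[k] = std::exp(lw[k] - mx); tot += lw[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  int pick = K;
  for (int k = 0; k <= K; ++k) {
    acc += lw[k];
    if (u <= acc) { pick = k; break; }
  }
  st.add(i, pick, x);
}

static void sweep(State& st, const int* x, double alpha, double beta,
                  bool use_lik, double log_fnew, bool random_scan) {
  std::vector<int> ord(st.N);
  for (int i = 0; i < st.N; ++i) ord[i] = i;
  if (random_scan) {  // Fisher-Yates with R RNG
    for (int i = st.N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
  }
  for (int i = 0; i < st.N; ++i) {
    st.remove(ord[i], x);
    seat_item(st, ord[i], x, alpha, beta, use_lik, log_fnew);
  }
}

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix X, IntegerVector V, double alpha, double beta,
                   int burn_in, int thinning, int n_samples,
                   bool prior_only, bool init_with_likelihood, bool random_scan) {
  int N = X.nrow(), D = X.ncol();
  std::vector<int> Vv(V.begin(), V.end());
  // row-major copy of the 0-based response codes
  std::vector<int> x(N * D);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < D; ++d)
      x[i * D + d] = X(i, d);
  double log_fnew = 0.0;  // prior predictive: prod_d 1/V_d for any beta
  for (int d = 0; d < D; ++d) log_fnew -= std::log((double)Vv[d]);

  State st(N, Vv);
  bool use_lik = !prior_only;
  for (int i = 0; i < N; ++i)  // sequential initial placement
    seat_item(st, i, x.data(), alpha, beta, use_lik && init_with_likelihood, log_fnew);
  for (int b = 0; b < burn_in; ++b) {
    sweep(st, x.data(), alpha, beta, use_lik, log_fnew, random_scan);
    if (b % 50 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out(n_samples, N);
  IntegerVector ktrace(n_samples);
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thinning; ++t)
      sweep(st, x.data(), alpha, beta, use_lik, log_fnew, random_scan);
    for (int i = 0; i < N; ++i) out(s, i) = st.assign[i] + 1;
    ktrace[s] = st.K();
    if (s % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["partitions"] = out, _["k_trace"] = ktrace);
}
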