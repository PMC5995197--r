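#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Total data log-likelihood of an event sequence.
// logpe, logpn: J x l matrices of log event / log non-event densities
// (columns in the original region order). seq holds 0-based column indices:
// seq[0] is the first region to become abnormal. logprior has length l+1
// (stages 0..l). Per scan, stage terms are built from prefix sums of the
// event logs and suffix sums of the non-event logs, then combined by
// log-sum-exp; O(l) per scan.
static double seq_ll(const NumericMatrix& logpe, const NumericMatrix& logpn,
                     const std::vector<int>& seq, const NumericVector& logprior) {
  const int J = logpe.nrow();
  const int l = (int) seq.size();
  std::vector<double> A(l + 1), B(l + 1);
  double total = 0.0;
  for (int j = 0; j < J; ++j) {
    A[0] = 0.0; B[0] = 0.0;
    for (int i = 0; i < l; ++i) {
      const int r = seq[i];
      A[i + 1] = A[i] + logpe(j, r);
      B[i + 1] = B[i] + logpn(j, r);
    }
    const double Btot = B[l];
    double m = R_NegInf;
    for (int k = 0; k <= l; ++k) {
      const double t = logprior[k] + A[k] + Btot - B[k];
      if (t > m) m = t;
    }
    double s = 0.0;
    for (int k = 0; k <= l; ++k)
      s += std::exp(logprior[k] + A[k] + Btot - B[k] - m);
    total += m + std::log(s);
  }
  return total;
}

static inline int rand_index(int l) {
  int i = (int) (unif_rand() * l);
  return (i >= l) ? l - 1 : i;
}

// [[Rcpp::export]]
double seq_loglik_cpp(NumericMatrix logpe, NumericMatrix logpn,
                      IntegerVector seq1, NumericVector logprior) {
  std::vector<int> seq(seq1.size());
  for (int i = 0; i < seq1.size(); ++i) seq[i] = seq1[i] - 1;
  return seq_ll(logpe, logpn, seq, logprior);
}

// Greedy ascent from n_starts random permutations; each iteration proposes a
// random transposition, accepted only on a strict likelihood increase.
// [[Rcpp::export]]
List greedy_cpp(NumericMatrix logpe, NumericMatrix logpn, NumericVector logprior,
                int n_starts, int n_iter) {
  const int l = logpe.ncol();
  NumericVector finals(n_starts);
  NumericMatrix traces(n_starts, n_iter);
  List start_seqs(n_starts);
  std::vector<int> best(l);
  double best_ll = R_NegInf;

  for (int s = 0; s < n_starts; ++s) {
    IntegerVector p = Rcpp::sample(l, l, false);
    std::vector<int> perm(l);
    for (int i = 0; i < l; ++i) perm[i] = p[i] - 1;
    double cur = seq_ll(logpe, logpn, perm, logprior);
    for (int it = 0; it < n_iter; ++it) {
      if (l >= 2) {
        int a = rand_index(l);
        int b = rand_index(l);
        while (b == a) b = rand_index(l);
        std::swap(perm[a], perm[b]);
        const double cand = seq_ll(logpe, logpn, perm, logprior);
        if (cand > cur) cur = cand; else std::swap(perm[a], perm[b]);
      }
      traces(s, it) = cur;
    }
    finals[s] = cur;
    IntegerVector out(l);
    for (int i = 0; i < l; ++i) out[i] = perm[i] + 1;
    start_seqs[s] = out;
    if (cur > best_ll) { best_ll = cur; best = perm; }
  }
  IntegerVector best1(l);
  for (int i = 0; i < l; ++i) best1[i] = best[i] + 1;
  return List::create(_["sequence"] = best1,
                      _["loglik"] = best_ll,
                      _["start_loglik"] = finals,
                      _["trace"] = traces,
                      _["start_sequences"] = start_seqs);
}

// Metropolis-Hastings over permutations with the symmetric random
// transposition proposal and uniform prior; acceptance min(1, exp(dll)).
// [[Rcpp::export]]
List mcmc_cpp(NumericMatrix logpe, NumericMatrix logpn, NumericVector logprior,
              IntegerVector init1, int n_samples, int burn_in) {
  const int l = logpe.ncol();
  std::vector<int> cur(l);
  for (int i = 0; i < l; ++i) cur[i] = init1[i] - 1;
  double cur_ll = seq_ll(logpe, logpn, cur, logprior);

  IntegerMatrix samples(n_samples, l);
  NumericVector lls(n_samples);
  long accepted = 0;
  const long total = (long) n_samples + burn_in;
  for (long t = 0; t < total; ++t) {
    if (l >= 2) {
      int a = rand_index(l);
      int b = rand_index(l);
      while (b == a) b = rand_index(l);
      std::swap(cur[a], cur[b]);
      const double cand_ll = seq_ll(logpe, logpn, cur, logprior);
      if (std::log(unif_rand()) < cand_ll - cur_ll) {
        cur_ll = cand_ll;
        ++accepted;
      } else {
        std::swap(cur[a], cur[b]);
      }
    }
    if (t >= burn_in) {
      const int row = (int) (t - burn_in);
      for (int i = 0; i < l; ++i) samples(row, i) = cur[i] + 1;
      lls[row] = cur_ll;
    }
  }
  return List::create(_["samples"] = samples,
                      _["loglik"] = lls,
                      _["acceptance_rate"] = (double) accepted / (double) total);
}

// Stage log-likelihood profiles for every scan: profile[j, k+1] =
// sum_{i<=k} logpe(S(i), j) + sum_{i>k} logpn(S(i), j), k = 0..l.
// [[Rcpp::export]]
NumericMatrix stage_profiles_cpp(NumericMatrix logpe, NumericMatrix logpn,
                                 IntegerVector seq1) {
  const int J = logpe.nrow();
  const int l = seq1.size();
  NumericMatrix prof(J, l + 1);
  std::vector<double> A(l + 1), B(l + 1);
  for (int j = 0; j < J; ++j) {
    A[0] = 0.0; B[0] = 0.0;
    for (int i = 0; i < l; ++i) {
      const int r = seq1[i] - 1;
      A[i + 1] = A[i] + logpe(j, r);
      B[i + 1] = B[i] + logpn(j, r);
    }
    const double Btot = B[l];
    for (int k = 0; k <= l; ++k) prof(j, k) = A[k] + Btot - B[k];
  }
  return prof;
}
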