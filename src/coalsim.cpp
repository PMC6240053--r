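// Coalescent simulation core: single population, piecewise-constant diploid
// effective size, generalized / two-phase stepwise microsatellite mutation.
// Uses R's RNG throughout so set.seed() governs all output.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Draw an unsigned mutation step size: with probability p_single the step is
// exactly one repeat unit, otherwise geometric on {1,2,...} with success
// probability q_mult (P(S=s) = q (1-q)^(s-1)). GSM uses p_single = 0 and
// q_mult = 1 - gsm_par so that P(S >= 2) = gsm_par; SMM uses p_single = 1.
static inline int draw_step(double p_single, double q_mult) {
  int s;
  if (p_single >= 1.0 || R::unif_rand() < p_single) {
    s = 1;
  } else if (q_mult >= 1.0) {
    s = 1;
  } else {
    // R::rgeom counts failures before first success: support {0,1,...}
    s = 1 + (int) R::rgeom(q_mult);
  }
  return (R::unif_rand() < 0.5) ? -s : s;
}

// Kingman coalescent with piecewise-constant diploid size.
// epoch_start: ascending, epoch_start[0] == 0; epoch_N: diploid sizes.
// On return parent[i] is the parent node of i (root: -1), node_time[i] the
// node age in generations. Tips are nodes 0..n-1 (age 0); internal nodes are
// created in coalescence order so parent index > child index always.
static void sim_genealogy(int n,
                          const double* epoch_start, const double* epoch_N,
                          int n_epoch,
                          std::vector<int>& parent,
                          std::vector<double>& node_time) {
  const int total = 2 * n - 1;
  parent.assign(total, -1);
  node_time.assign(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;

  double t = 0.0;
  int k = n;
  int next_node = n;
  int ep = 0;

  while (k > 1) {
    while (ep + 1 < n_epoch && t >= epoch_start[ep + 1]) ++ep;
    double N = epoch_N[ep];
    double rate = (double) k * (k - 1) / 2.0 / (2.0 * N);
    double wait = R::exp_rand() / rate;
    double t_boundary = (ep + 1 < n_epoch) ? epoch_start[ep + 1] : R_PosInf;
    if (t + wait >= t_boundary) {  // no event in this epoch remnant
      t = t_boundary;
      ++ep;
      continue;
    }
    t += wait;
    int i = (int) (R::unif_rand() * k); if (i == k) i = k - 1;
    int j = (int) (R::unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    parent[a] = next_node;
    parent[b] = next_node;
    node_time[next_node] = t;
    // replace lineage i with the new node, drop j by swapping in the last
    active[i] = next_node;
    active[j] = active[k - 1];
    --k;
    ++next_node;
  }
}

// Drop mutations on a genealogy and return allele state per node.
// Root state fixed; states floored at 1 repeat unit.
static void mutate_tree(const std::vector<int>& parent,
                        const std::vector<double>& node_time,
                        double mu, double p_single, double q_mult,
                        int root_state, std::vector<int>& state) {
  const int total = (int) parent.size();
  state.assign(total, root_state);
  // parent index > child index, so a reverse sweep sees parents first
  for (int i = total - 2; i >= 0; --i) {
    double len = node_time[parent[i]] - node_time[i];
    int a = state[parent[i]];
    int nm = (int) R::rpois(mu * len);
    for (int m = 0; m < nm; ++m) a += draw_step(p_single, q_mult);
    if (a < 1) a = 1;
    state[i] = a;
  }
}

// Per-locus summary statistics from one gene-copy allele vector:
// k, allele size range r, unbiased Nei gene diversity, M = k/(r+1),
// proportion of alleles at sample frequency < 0.05.
static void locus_stats(std::vector<int>& alleles, double* out) {
  const int m = (int) alleles.size();
  std::sort(alleles.begin(), alleles.end());
  int k = 0;
  double sum_p2 = 0.0;
  int n_low = 0;
  int i = 0;
  while (i < m) {
    int j = i;
    while (j < m && alleles[j] == alleles[i]) ++j;
    double p = (double) (j - i) / m;
    sum_p2 += p * p;
    if (p < 0.05) ++n_low;
    ++k;
    i = j;
  }
  double r = (double) (alleles[m - 1] - alleles[0]);
  double he = (m > 1) ? ((double) m / (m - 1)) * (1.0 - sum_p2) : 0.0;
  out[0] = (double) k;
  out[1] = r;
  out[2] = he;
  out[3] = (double) k / (r + 1.0);
  out[4] = (double) n_low / k;
}

// [[Rcpp::export]]
List cpp_sim_genealogy(int n, NumericVector epoch_start, NumericVector epoch_N) {
  std::vector<int> parent;
  std::vector<double> node_time;
  sim_genealogy(n, epoch_start.begin(), epoch_N.begin(), epoch_start.size(),
                parent, node_time);
  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(node_time));
}

// [[Rcpp::export]]
IntegerVector cpp_mutate_tree(IntegerVector parent, NumericVector node_time,
                              double mu, double p_single, double q_mult,
                              int root_state) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(node_time.begin(), node_time.end());
  std::vector<int> state;
  mutate_tree(par, tim, mu, p_single, q_mult, root_state, state);
  return wrap(state);
}

// [[Rcpp::export]]
IntegerVector cpp_sim_locus(int n_copies, NumericVector epoch_start,
                            NumericVector epoch_N, double mu,
                            double p_single, double q_mult, int root_state) {
  std::vector<int> parent;
  std::vector<double> node_time;
  sim_genealogy(n_copies, epoch_start.begin(), epoch_N.begin(),
                epoch_start.size(), parent, node_time);
  std::vector<int> state;
  mutate_tree(parent, node_time, mu, p_single, q_mult, root_state, state);
  return IntegerVector(state.begin(), state.begin() + n_copies);
}

// Simulate whole datasets and return the 5 mean summary statistics per
// parameter row. Epoch matrices: one row per simulation, n_epoch columns.
// [[Rcpp::export]]
NumericMatrix cpp_batch_sumstats(int n_ind, int n_loci,
                                 NumericMatrix epoch_start,
                                 NumericMatrix epoch_N,
                                 NumericVector mu,
                                 NumericVector p_single,
                                 NumericVector q_mult,
                                 int root_state) {
  const int n_sims = epoch_start.nrow();
  const int n_epoch = epoch_start.ncol();
  const int n_copies = 2 * n_ind;
  NumericMatrix out(n_sims, 5);
  std::vector<double> es(n_epoch), eN(n_epoch);
  std::vector<int> parent, state;
  std::vector<double> node_time;
  std::vector<int> copies(n_copies);
  double st[5];

  for (int s = 0; s < n_sims; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    for (int e = 0; e < n_epoch; ++e) {
      es[e] = epoch_start(s, e);
      eN[e] = epoch_N(s, e);
    }
    double acc[5] = {0, 0, 0, 0, 0};
    for (int l = 0; l < n_loci; ++l) {
      sim_genealogy(n_copies, es.data(), eN.data(), n_epoch, parent, node_time);
      mutate_tree(parent, node_time, mu[s], p_single[s], q_mult[s],
                  root_state, state);
      std::copy(state.begin(), state.begin() + n_copies, copies.begin());
      locus_stats(copies, st);
      for (int q = 0; q < 5; ++q) acc[q] += st[q];
    }
    for (int q = 0; q < 5; ++q) out(s, q) = acc[q] / n_loci;
  }
  colnames(out) = CharacterVector::create("k", "r", "He", "M", "lfa");
  return out;
}

// one constant-size locus at scaled mutation rate theta = 4*N*mu
// (N = 1 diploid, mu = theta/4); fills `st` with the 5 locus statistics
static void sim_locus_theta(int n_copies, double theta, double p_single,
                            double q_mult, std::vector<int>& parent,
                            std::vector<double>& node_time,
                            std::vector<int>& state,
                            std::vector<int>& copies, double* st) {
  double es = 0.0, eN = 1.0;
  sim_genealogy(n_copies, &es, &eN, 1, parent, node_time);
  mutate_tree(parent, node_time, theta / 4.0, p_single, q_mult, 1000, state);
  std::copy(state.begin(), state.begin() + n_copies, copies.begin());
  locus_stats(copies, st);
}

// Equilibrium-heterozygosity simulation conditional on allele number k
// (heterozygosity-excess test): the scaled mutation rate theta is first
// calibrated by stochastic bisection so that the mean simulated allele count
// equals k, then loci are simulated at that theta and replicates with
// exactly k alleles are retained; their unbiased Nei gene diversities form
// the H_eq draws. Conditioning by rejection samples the true stationary
// distribution of He given K = k (up to the weak residual dependence of
// He | K on theta).
// [[Rcpp::export]]
NumericVector cpp_heq_simulate(int n_copies, int k, double p_single,
                               double q_mult, int n_sims, int pilot_sims,
                               double max_attempt_factor) {
  std::vector<int> parent, state;
  std::vector<double> node_time;
  std::vector<int> copies(n_copies);
  double st[5];

  // calibrate theta: E[K | theta] is increasing in theta
  double lo = 1e-4, hi = 1e4;
  for (int it = 0; it < 20; ++it) {
    Rcpp::checkUserInterrupt();
    double mid = std::sqrt(lo * hi);
    double acc = 0.0;
    for (int b = 0; b < pilot_sims; ++b) {
      sim_locus_theta(n_copies, mid, p_single, q_mult, parent, node_time,
                      state, copies, st);
      acc += st[0];
    }
    if (acc / pilot_sims < k) lo = mid; else hi = mid;
  }
  double theta = std::sqrt(lo * hi);

  NumericVector out(n_sims);
  long max_attempt = (long) (max_attempt_factor * n_sims);
  long attempts = 0;
  int got = 0;
  while (got < n_sims) {
    if (attempts % 256 == 0) Rcpp::checkUserInterrupt();
    if (++attempts > max_attempt)
      stop("conditioning on k = %d alleles accepted only %d of %d draws "
           "after %ld simulations", k, got, n_sims, attempts);
    sim_locus_theta(n_copies, theta, p_single, q_mult, parent, node_time,
                    state, copies, st);
    if ((int) st[0] == k) out[got++] = st[2];
  }
  return out;
}
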