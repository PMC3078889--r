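#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Backward-in-time structured coalescent for two demes (0 = focal/"crossriver",
// 1 = outgroup/"western") that merge into a single ancestral deme at t_div,
// with serial sampling, an exponential size change in deme 0 between t = 0 and
// t = t_bot (size n_cr_now at present, n_cr_now * ratio at t_bot and earlier),
// and either symmetric migration on [t_mig, t_div) at backward rate
// two_nm / (2 N_deme(t)) per lineage (model_kind 0) or a single admixture
// pulse at t_admix moving each deme-0 lineage to deme 1 with probability
// gamma_admix (model_kind 1). Mutations follow a stepwise model: Poisson
// (mu * branch length) events, each +-1 repeat with probability 1/2.
//
// Uses R's RNG throughout so results are reproducible via set.seed().

static int pick_one(int k) {
  int i = (int)std::floor(unif_rand() * k);
  return (i >= k) ? (k - 1) : i;
}

// [[Rcpp::export(name = ".simulateLocusCpp")]]
List simulate_locus_cpp(IntegerVector samp_deme, NumericVector samp_time,
                                 double n_cr_now, double ratio, double n_ancestral,
                                 double n_western, double t_div, double t_bot,
                                 double two_nm, double t_mig, double t_admix,
                                 double gamma_admix, int model_kind, double mu,
                                 int root_size) {
  const int n = samp_deme.size();
  if (n < 1) stop("empty sampling scheme");
  const int n_nodes = 2 * n - 1;

  std::vector<int> parent(n_nodes, -1);
  std::vector<double> node_time(n_nodes, 0.0), brlen(n_nodes, 0.0);
  for (int i = 0; i < n; ++i) node_time[i] = samp_time[i];

  // sample entry order (serial sampling)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return samp_time[a] < samp_time[b]; });

  std::vector<int> act[2];
  int next_samp = 0;
  int next_node = n;
  double t = 0.0;
  const double r_bot = (t_bot > 0.0 && ratio > 1.0) ? std::log(ratio) / t_bot : 0.0;
  const double n_cr_old = n_cr_now * ratio;
  bool merged = false;
  bool admix_done = (model_kind != 1) || (gamma_admix <= 0.0);

  // lineages entering at or before time tt
  auto enter_samples = [&](double tt) {
    while (next_samp < n && samp_time[order[next_samp]] <= tt) {
      int id = order[next_samp++];
      int d = merged ? 0 : samp_deme[id];
      act[d].push_back(id);
    }
  };
  enter_samples(0.0);

  for (;;) {
    int k0 = (int)act[0].size(), k1 = (int)act[1].size();
    if (k0 + k1 <= 1 && next_samp >= n) break;

    // end of the current constant-regime segment
    double seg_end = R_PosInf;
    if (next_samp < n) seg_end = std::min(seg_end, samp_time[order[next_samp]]);
    if (!merged) {
      seg_end = std::min(seg_end, t_div);
      if (t < t_bot) seg_end = std::min(seg_end, t_bot);
      if (model_kind == 0 && t < t_mig) seg_end = std::min(seg_end, t_mig);
      if (!admix_done && t < t_admix) seg_end = std::min(seg_end, t_admix);
    }

    bool mig_on = (!merged && model_kind == 0 && two_nm > 0.0 &&
                   t >= t_mig && t < t_div);

    double c0 = 0.5 * (double)k0 * (k0 - 1);
    double m0 = mig_on ? (double)k0 * two_nm : 0.0;
    double A0 = c0 + m0;
    double c1 = merged ? 0.0 : 0.5 * (double)k1 * (k1 - 1);
    double m1 = mig_on ? (double)k1 * two_nm : 0.0;
    double A1 = c1 + m1;

    double s0 = R_PosInf, s1 = R_PosInf;
    if (A0 > 0.0) {
      double E = exp_rand();
      if (merged) {
        s0 = 2.0 * n_ancestral * E / A0;
      } else if (t < t_bot && r_bot > 0.0) {
        // exponential epoch: N(u) = n_cr_now * exp(r_bot * u), closed-form
        // inversion of the integrated rate
        double arg = std::exp(-r_bot * t) - 2.0 * n_cr_now * r_bot * E / A0;
        s0 = (arg > 0.0) ? (-std::log(arg) / r_bot - t) : R_PosInf;
      } else if (t < t_bot) {
        s0 = 2.0 * n_cr_now * E / A0;  // ratio == 1
      } else {
        s0 = 2.0 * n_cr_old * E / A0;
      }
    }
    if (A1 > 0.0) s1 = exp_rand() * 2.0 * n_western / A1;

    double s = std::min(s0, s1);
    if (!(t + s < seg_end)) {
      // advance to the boundary and process whatever applies there
      if (!R_FINITE(seg_end)) stop("internal error: open-ended segment with no events");
      t = seg_end;
      enter_samples(t);
      if (!admix_done && t >= t_admix && t < t_div) {
        std::vector<int> stay;
        for (size_t j = 0; j < act[0].size(); ++j) {
          if (unif_rand() < gamma_admix) act[1].push_back(act[0][j]);
          else stay.push_back(act[0][j]);
        }
        act[0].swap(stay);
        admix_done = true;
      }
      if (!merged && t >= t_div) {
        for (size_t j = 0; j < act[1].size(); ++j) act[0].push_back(act[1][j]);
        act[1].clear();
        merged = true;
      }
      continue;
    }

    t += s;
    int d = (s0 <= s1) ? 0 : 1;
    double coal_part = (d == 0) ? c0 : c1;
    double tot = (d == 0) ? A0 : A1;
    int k = (int)act[d].size();
    if (unif_rand() * tot < coal_part) {
      // coalescence: merge two random lineages of deme d
      int i1 = pick_one(k);
      int c_a = act[d][i1];
      act[d][i1] = act[d].back();
      act[d].pop_back();
      int i2 = pick_one(k - 1);
      int c_b = act[d][i2];
      int v = next_node++;
      node_time[v] = t;
      parent[c_a] = v;
      brlen[c_a] = t - node_time[c_a];
      parent[c_b] = v;
      brlen[c_b] = t - node_time[c_b];
      act[d][i2] = v;
    } else {
      // migration: move a random lineage to the other deme
      int i1 = pick_one(k);
      int lin = act[d][i1];
      act[d][i1] = act[d].back();
      act[d].pop_back();
      act[1 - d].push_back(lin);
    }
  }

  if (next_node != n_nodes && n > 1)
    stop("internal error: genealogy did not fully coalesce");

  // drop stepwise mutations on every branch, root value fixed
  std::vector<int> allele(n_nodes);
  allele[n_nodes - 1] = root_size;
  for (int i = n_nodes - 2; i >= 0; --i) {
    int k = (int)R::rpois(mu * brlen[i]);
    int up = (k > 0) ? (int)R::rbinom((double)k, 0.5) : 0;
    allele[i] = allele[parent[i]] + 2 * up - k;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = allele[i];
  NumericVector coal(n - 1 > 0 ? n - 1 : 0);
  for (int i = n; i < n_nodes; ++i) coal[i - n] = node_time[i];
  return List::create(_["alleles"] = out, _["coal_times"] = coal);
}
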