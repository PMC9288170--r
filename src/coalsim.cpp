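// Two-population isolation coalescent with finite-sites mutation.
//
// Conventions (see ?simScale): the coalescent time unit is fixed by a
// reference per-site theta (theta_ref): mutation rate per site per time
// unit is theta_ref/2, and the per-pair coalescence rate in a deme with
// per-site theta_j is theta_ref/theta_j.  Under this scaling
// E[pi_within_j] = theta_j and E[pi_net] = theta_ref * tau + thetaA -
// (theta1+theta2)/2.
//
// All randomness goes through R's RNG so that set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

// Simulate the genealogy of n1 + n2 tips.  Tips 0..n1-1 belong to deme 1
// (west), tips n1..n1+n2-1 to deme 2 (east).  Internal nodes are created
// in increasing time order, so parent index > child index always holds.
// Root has parent -1.  Times are coalescent units, tips at 0.
void sim_genealogy(int n1, int n2, double th1, double th2, double thA,
                   double tau, double theta_ref,
                   std::vector<int> &parent, std::vector<double> &ntime) {
  const int n = n1 + n2;
  const int nnode = 2 * n - 1;
  parent.assign(nnode, -1);
  ntime.assign(nnode, 0.0);

  std::vector<int> a1, a2;
  for (int i = 0; i < n1; ++i) a1.push_back(i);
  for (int i = 0; i < n2; ++i) a2.push_back(n1 + i);

  double t = 0.0;
  int next = n;

  auto merge = [&](std::vector<int> &act, double when) {
    int i = (int)std::floor(unif_rand() * act.size());
    int j = (int)std::floor(unif_rand() * (act.size() - 1));
    if (j >= i) ++j;
    int u = act[i], v = act[j];
    parent[u] = next; parent[v] = next;
    ntime[next] = when;
    if (i > j) std::swap(i, j);
    act.erase(act.begin() + j);
    act[i] = next;
    ++next;
  };

  // isolation phase: coalescence only within demes, until tau
  while (t < tau) {
    double k1 = (double)a1.size(), k2 = (double)a2.size();
    double r1 = k1 * (k1 - 1.0) / 2.0 * theta_ref / th1;
    double r2 = k2 * (k2 - 1.0) / 2.0 * theta_ref / th2;
    double rt = r1 + r2;
    if (rt <= 0.0) break;
    double dt = exp_rand() / rt;
    if (t + dt >= tau) break;
    t += dt;
    if (unif_rand() * rt < r1) merge(a1, t); else merge(a2, t);
  }

  // ancestral phase: pool everything
  t = tau;
  std::vector<int> pool(a1);
  pool.insert(pool.end(), a2.begin(), a2.end());
  while (pool.size() > 1) {
    double k = (double)pool.size();
    double rt = k * (k - 1.0) / 2.0 * theta_ref / thA;
    t += exp_rand() / rt;
    merge(pool, t);
  }
}

inline int mutate_base(int b, double kappa) {
  // K80-style with equal base frequencies; kappa = 1 reduces to JC.
  // Encoding A=0, C=1, G=2, T=3; transitions are b XOR 2.
  double u = unif_rand() * (kappa + 2.0);
  if (u < kappa) return b ^ 2;
  int par = 1 - (b & 1);               // opposite purine/pyrimidine class
  return par + 2 * (unif_rand() < 0.5 ? 0 : 1);
}

struct MutEvent { int node; double time; };

// Drop Poisson mutations on the tree and return, per mutated site, the
// tip states.  `states` maps site -> vector of tip base codes.
void mutate_tree(const std::vector<int> &parent,
                 const std::vector<double> &ntime,
                 int ntips, int L, double theta_ref, double kappa,
                 std::map<int, std::vector<int> > &states,
                 std::vector<int> *rootbase = nullptr) {
  const int nnode = (int)parent.size();
  std::vector<double> blen(nnode, 0.0), cum(nnode, 0.0);
  double total = 0.0;
  for (int v = 0; v < nnode; ++v) {
    if (parent[v] >= 0) blen[v] = ntime[parent[v]] - ntime[v];
    total += blen[v];
    cum[v] = total;
  }
  double mu_tree = total * theta_ref / 2.0 * (double)L;
  int M = (int)R::rpois(mu_tree);

  std::map<int, std::vector<MutEvent> > by_site;
  for (int m = 0; m < M; ++m) {
    double u = unif_rand() * total;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= nnode) v = nnode - 1;
    int site = (int)std::floor(unif_rand() * L);
    double tp = ntime[v] + unif_rand() * blen[v];
    by_site[site].push_back(MutEvent{v, tp});
  }

  std::vector<int> st(nnode);
  for (std::map<int, std::vector<MutEvent> >::iterator it = by_site.begin();
       it != by_site.end(); ++it) {
    int site = it->first;
    std::vector<MutEvent> &ev = it->second;
    int rb = (int)std::floor(unif_rand() * 4.0);
    if (rootbase) (*rootbase)[site] = rb;
    // parent index always exceeds child index, so a single descending
    // sweep visits parents first
    for (int v = nnode - 1; v >= 0; --v) {
      int b = (parent[v] < 0) ? rb : st[parent[v]];
      // events on the branch above v, applied forward in real time,
      // i.e. by decreasing coalescent time
      std::vector<MutEvent*> mine;
      for (size_t k = 0; k < ev.size(); ++k)
        if (ev[k].node == v) mine.push_back(&ev[k]);
      std::sort(mine.begin(), mine.end(),
                [](MutEvent *a, MutEvent *b2) { return a->time > b2->time; });
      for (size_t k = 0; k < mine.size(); ++k) b = mutate_base(b, kappa);
      st[v] = b;
    }
    std::vector<int> tip(ntips);
    for (int i = 0; i < ntips; ++i) tip[i] = st[i];
    states[site] = tip;
  }
}

// pi_w1, pi_w2, pi_b, pi_net, theta_w, S from sparse site states
void stats_from_states(const std::map<int, std::vector<int> > &states,
                       int n1, int n2, int L, double out[6]) {
  const int n = n1 + n2;
  double dw1 = 0.0, dw2 = 0.0, db = 0.0;
  int S = 0;
  for (std::map<int, std::vector<int> >::const_iterator it = states.begin();
       it != states.end(); ++it) {
    const std::vector<int> &tip = it->second;
    int c1[4] = {0, 0, 0, 0}, c2[4] = {0, 0, 0, 0};
    for (int i = 0; i < n1; ++i) c1[tip[i]]++;
    for (int i = n1; i < n; ++i) c2[tip[i]]++;
    int distinct = 0;
    double s1 = 0.0, s2 = 0.0, sb = 0.0;
    for (int b = 0; b < 4; ++b) {
      if (c1[b] + c2[b] > 0) ++distinct;
      s1 += c1[b] * (c1[b] - 1.0) / 2.0;
      s2 += c2[b] * (c2[b] - 1.0) / 2.0;
      sb += (double)c1[b] * c2[b];
    }
    if (distinct >= 2) ++S;
    dw1 += n1 * (n1 - 1.0) / 2.0 - s1;
    dw2 += n2 * (n2 - 1.0) / 2.0 - s2;
    db  += (double)n1 * n2 - sb;
  }
  double p1 = n1 * (n1 - 1.0) / 2.0, p2 = n2 * (n2 - 1.0) / 2.0;
  double pw1 = p1 > 0 ? dw1 / (p1 * L) : NA_REAL;
  double pw2 = p2 > 0 ? dw2 / (p2 * L) : NA_REAL;
  double pb = db / ((double)n1 * n2 * L);
  double w1 = p1 > 0 ? pw1 : 0.0, w2 = p2 > 0 ? pw2 : 0.0;
  double an = 0.0;
  for (int i = 1; i < n; ++i) an += 1.0 / i;
  out[0] = pw1; out[1] = pw2; out[2] = pb;
  out[3] = pb - (w1 + w2) / 2.0;
  out[4] = S / ((double)L * an);
  out[5] = (double)S;
}

} // namespace

// [[Rcpp::export(name = ".simGenealogyCpp")]]
List sim_genealogy_cpp(int n1, int n2, double theta1, double theta2,
                       double thetaA, double tau, double theta_ref) {
  std::vector<int> parent; std::vector<double> ntime;
  sim_genealogy(n1, n2, theta1, theta2, thetaA, tau, theta_ref, parent, ntime);
  IntegerVector p(parent.size());
  NumericVector tt(ntime.size());
  for (size_t i = 0; i < parent.size(); ++i) {
    p[i] = parent[i] < 0 ? NA_INTEGER : parent[i] + 1;  // 1-based for R
    tt[i] = ntime[i];
  }
  return List::create(_["parent"] = p, _["nodeTime"] = tt);
}

// [[Rcpp::export(name = ".mutateTreeCpp")]]
IntegerMatrix mutate_tree_cpp(IntegerVector parent, NumericVector nodeTime,
                              int ntips, int L, double theta_ref,
                              double kappa) {
  const int nnode = parent.size();
  std::vector<int> par(nnode);
  std::vector<double> tim(nnode);
  for (int i = 0; i < nnode; ++i) {
    par[i] = parent[i] == NA_INTEGER ? -1 : parent[i] - 1;
    tim[i] = nodeTime[i];
  }
  std::map<int, std::vector<int> > states;
  std::vector<int> rootbase(L, -1);
  mutate_tree(par, tim, ntips, L, theta_ref, kappa, states, &rootbase);
  IntegerMatrix seq(ntips, L);
  for (int s = 0; s < L; ++s) {
    int rb = rootbase[s] >= 0 ? rootbase[s]
                              : (int)std::floor(unif_rand() * 4.0);
    std::map<int, std::vector<int> >::iterator it = states.find(s);
    for (int i = 0; i < ntips; ++i)
      seq(i, s) = (it == states.end()) ? rb : it->second[i];
  }
  return seq;
}

// [[Rcpp::export(name = ".simTaxonStatsCpp")]]
NumericVector sim_taxon_stats_cpp(int n1, int n2, int L, double theta1,
                                  double theta2, double thetaA, double tau,
                                  double theta_ref, double kappa) {
  std::vector<int> parent; std::vector<double> ntime;
  sim_genealogy(n1, n2, theta1, theta2, thetaA, tau, theta_ref, parent, ntime);
  std::map<int, std::vector<int> > states;
  mutate_tree(parent, ntime, n1 + n2, L, theta_ref, kappa, states);
  double out[6];
  stats_from_states(states, n1, n2, L, out);
  NumericVector res(6);
  for (int i = 0; i < 6; ++i) res[i] = out[i];
  res.names() = CharacterVector::create("pi_w1", "pi_w2", "pi_b", "pi_net",
                                        "theta_w", "s");
  return res;
}

// Bulk prior-predictive table.  Each row: one hyperprior draw (Psi uniform
// on 1..nTaxa, pulse times Uniform(0, tauMax], taxon->pulse assignment
// uniform over surjections by rejection, per-taxon thetas iid
// Uniform(thetaLo, thetaHi)), the induced tau vector / Omega / E[tau],
// and the 8-number aggregate statistic vector (cross-taxon mean and
// population variance of pi_b, pi_w1+pi_w2, pi_net, theta_w).
// [[Rcpp::export(name = ".buildPriorTableCpp")]]
NumericMatrix build_prior_table_cpp(IntegerVector n1, IntegerVector n2,
                                    IntegerVector L, double tauMax,
                                    double thetaLo, double thetaHi,
                                    int nSims, double theta_ref,
                                    double kappa) {
  const int nt = n1.size();
  const int ncol = 3 + 2 * nt + 8;
  NumericMatrix out(nSims, ncol);
  std::vector<int> assign(nt);
  std::vector<double> pulse(nt);

  for (int s = 0; s < nSims; ++s) {
    int psi = 1 + (int)std::floor(unif_rand() * nt);
    if (psi > nt) psi = nt;
    for (int p = 0; p < psi; ++p) pulse[p] = unif_rand() * tauMax;
    // uniform over surjections
    bool ok = false;
    while (!ok) {
      std::vector<bool> hit(psi, false);
      for (int i = 0; i < nt; ++i) {
        int a = (int)std::floor(unif_rand() * psi);
        if (a >= psi) a = psi - 1;
        assign[i] = a; hit[a] = true;
      }
      ok = true;
      for (int p = 0; p < psi; ++p) if (!hit[p]) { ok = false; break; }
    }
    double mtau = 0.0;
    for (int i = 0; i < nt; ++i) mtau += pulse[assign[i]];
    mtau /= nt;
    double vtau = 0.0;
    for (int i = 0; i < nt; ++i) {
      double d = pulse[assign[i]] - mtau; vtau += d * d;
    }
    vtau /= nt;
    out(s, 0) = (double)psi;
    out(s, 1) = mtau > 0 ? vtau / mtau : 0.0;
    out(s, 2) = mtau;

    double m[4] = {0, 0, 0, 0}, m2[4] = {0, 0, 0, 0};
    for (int i = 0; i < nt; ++i) {
      double tau_i = pulse[assign[i]];
      out(s, 3 + i) = tau_i;
      out(s, 3 + nt + i) = (double)(assign[i] + 1);
      double th1 = thetaLo + unif_rand() * (thetaHi - thetaLo);
      double th2 = thetaLo + unif_rand() * (thetaHi - thetaLo);
      double thA = thetaLo + unif_rand() * (thetaHi - thetaLo);
      std::vector<int> parent; std::vector<double> ntime;
      sim_genealogy(n1[i], n2[i], th1, th2, thA, tau_i, theta_ref,
                    parent, ntime);
      std::map<int, std::vector<int> > states;
      mutate_tree(parent, ntime, n1[i] + n2[i], L[i], theta_ref, kappa,
                  states);
      double st[6];
      stats_from_states(states, n1[i], n2[i], L[i], st);
      double v4[4] = {st[2], st[0] + st[1], st[3], st[4]};
      for (int k = 0; k < 4; ++k) { m[k] += v4[k]; m2[k] += v4[k] * v4[k]; }
    }
    for (int k = 0; k < 4; ++k) {
      double mu = m[k] / nt;
      out(s, 3 + 2 * nt + 2 * k) = mu;
      out(s, 3 + 2 * nt + 2 * k + 1) = m2[k] / nt - mu * mu;
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
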