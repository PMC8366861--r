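#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Backward-time structured coalescent over demes with piecewise-constant
// gene-copy numbers G (coalescence rate k(k-1)/2 / G per generation) and a
// sorted event list. Event matrix columns:
//   0: time (generations, ascending)
//   1: type (0 = resize, 1 = admixture, 2 = merge)
//   2: d1 (0-based deme the event acts on)
//   3: d2 (admixture: first parent; merge: sink deme)
//   4: d3 (admixture: second parent; else unused)
//   5: x  (resize: new G; admixture: probability a lineage joins d2)
//
// Uses R's RNG so results are reproducible under set.seed().

struct Tree {
  std::vector<int> parent;     // -1 for root
  std::vector<double> time;    // node ages, tips at their deme's start (0)
  int n_tips;
};

static Tree sim_tree(const IntegerVector& n_per_deme,
                     const NumericVector& G0,
                     const NumericMatrix& events) {
  const int D = n_per_deme.size();
  int n = 0;
  for (int d = 0; d < D; ++d) n += n_per_deme[d];
  if (n < 2) stop("need at least 2 sampled gene copies");

  Tree tr;
  tr.n_tips = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  std::vector<double> G(G0.begin(), G0.end());
  std::vector< std::vector<int> > pool(D);
  int id = 0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < n_per_deme[d]; ++k) pool[d].push_back(id++);

  int next_node = n, ev = 0, alive = n;
  const int nE = events.nrow();
  double t = 0.0;

  while (alive > 1 || ev < nE) {
    double rate = 0.0;
    for (int d = 0; d < D; ++d) {
      const double k = (double) pool[d].size();
      if (k > 1.0 && G[d] > 0.0) rate += k * (k - 1.0) / (2.0 * G[d]);
    }
    const double t_ev = (ev < nE) ? events(ev, 0) : R_PosInf;
    double dt = (rate > 0.0) ? exp_rand() / rate : R_PosInf;

    if (t + dt < t_ev) {
      t += dt;
      // choose deme proportional to its coalescence rate
      double u = unif_rand() * rate, acc = 0.0;
      int dc = -1;
      for (int d = 0; d < D; ++d) {
        const double k = (double) pool[d].size();
        if (k > 1.0 && G[d] > 0.0) {
          acc += k * (k - 1.0) / (2.0 * G[d]);
          if (u <= acc) { dc = d; break; }
        }
      }
      if (dc < 0) dc = D - 1;
      std::vector<int>& P = pool[dc];
      int i = (int) std::floor(unif_rand() * P.size());
      int j = (int) std::floor(unif_rand() * (P.size() - 1));
      if (j >= i) ++j;
      const int a = P[i], b = P[j];
      const int node = next_node++;
      tr.parent[a] = node; tr.parent[b] = node;
      tr.time[node] = t;
      if (i > j) std::swap(i, j);
      P.erase(P.begin() + j);
      P.erase(P.begin() + i);
      P.push_back(node);
      --alive;
    } else if (R_finite(t_ev)) {
      t = t_ev;
      const int type = (int) events(ev, 1);
      const int d1 = (int) events(ev, 2);
      if (type == 0) {                      // resize
        G[d1] = events(ev, 5);
      } else if (type == 1) {               // admixture: d1 splits to d2/d3
        const int d2 = (int) events(ev, 3);
        const int d3 = (int) events(ev, 4);
        const double pr = events(ev, 5);
        for (size_t k = 0; k < pool[d1].size(); ++k) {
          if (unif_rand() < pr) pool[d2].push_back(pool[d1][k]);
          else pool[d3].push_back(pool[d1][k]);
        }
        pool[d1].clear();
      } else {                              // merge: d1 into d2
        const int d2 = (int) events(ev, 3);
        for (size_t k = 0; k < pool[d1].size(); ++k)
          pool[d2].push_back(pool[d1][k]);
        pool[d1].clear();
      }
      ++ev;
    } else {
      stop("coalescent stalled: no rate and no pending events");
    }
  }
  return tr;
}

// Drop generalized-stepwise mutations on the tree: Poisson(mu * branch
// length) events per branch, step size 1 + Geometric(P), sign equiprobable,
// reflection at a floor of 2 repeat units.
static IntegerVector mutate_tree_internal(const Tree& tr, double mu, double P,
                                          int root_state) {
  const int m = (int) tr.parent.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return tr.time[a] > tr.time[b];
  });
  std::vector<int> state(m, root_state);
  for (int k = 0; k < m; ++k) {
    const int v = ord[k];
    if (tr.parent[v] < 0) { state[v] = root_state; continue; }
    const double bl = tr.time[tr.parent[v]] - tr.time[v];
    int s = state[tr.parent[v]];
    const int nmut = (int) R::rpois(mu * bl);
    for (int j = 0; j < nmut; ++j) {
      int step = 1;
      if (P > 0.0) step += (int) R::rgeom(1.0 - P);
      if (unif_rand() < 0.5) step = -step;
      s += step;
      if (s < 2) s = 4 - s;   // reflect about the 2-repeat floor
    }
    state[v] = s;
  }
  IntegerVector out(tr.n_tips);
  for (int i = 0; i < tr.n_tips; ++i) out[i] = state[i];
  return out;
}

// [[Rcpp::export]]
List cpp_sim_tree(IntegerVector n_per_deme, NumericVector G0,
                  NumericMatrix events) {
  Tree tr = sim_tree(n_per_deme, G0, events);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["n_tips"] = tr.n_tips);
}

// [[Rcpp::export]]
IntegerVector cpp_mutate_tree(IntegerVector parent, NumericVector node_time,
                              int n_tips, double mu, double P,
                              int root_state) {
  Tree tr;
  tr.parent.assign(parent.begin(), parent.end());
  tr.time.assign(node_time.begin(), node_time.end());
  tr.n_tips = n_tips;
  return mutate_tree_internal(tr, mu, P, root_state);
}

// One full dataset: L_nu independent nuclear gene trees, one shared
// chloroplast tree carrying L_cp fully linked loci.
// [[Rcpp::export]]
List cpp_sim_msat(IntegerVector n_nu, NumericVector G_nu, NumericMatrix ev_nu,
                  int L_nu, double mu_nu, double P_nu,
                  IntegerVector n_cp, NumericVector G_cp, NumericMatrix ev_cp,
                  int L_cp, double mu_cp, double P_cp, int root_state) {
  int ntot_nu = 0, ntot_cp = 0;
  for (int d = 0; d < n_nu.size(); ++d) ntot_nu += n_nu[d];
  for (int d = 0; d < n_cp.size(); ++d) ntot_cp += n_cp[d];
  IntegerMatrix nu(ntot_nu, L_nu), cp(ntot_cp, L_cp);
  for (int l = 0; l < L_nu; ++l) {
    Tree tr = sim_tree(n_nu, G_nu, ev_nu);
    IntegerVector al = mutate_tree_internal(tr, mu_nu, P_nu, root_state);
    for (int i = 0; i < ntot_nu; ++i) nu(i, l) = al[i];
  }
  if (L_cp > 0) {
    Tree tr = sim_tree(n_cp, G_cp, ev_cp);
    for (int l = 0; l < L_cp; ++l) {
      IntegerVector al = mutate_tree_internal(tr, mu_cp, P_cp, root_state);
      for (int i = 0; i < ntot_cp; ++i) cp(i, l) = al[i];
    }
  }
  return List::create(_["nu"] = nu, _["cp"] = cp);
}

// Summary statistics on a gene-copy allele matrix (rows = gene copies,
// cols = loci, NA allowed), demes 0-based. Per deme (means over loci):
// allele number, unbiased genic diversity, allele-size variance,
// Garza-Williamson M. Per ordered pair i<j: WC haploid theta (multilocus,
// summed components), pooled genic diversity, (delta-mu)^2, and
// 1 - sum(min(p1,p2)) shared-allele distance.
// [[Rcpp::export]]
NumericVector cpp_gene_stats(IntegerMatrix alleles, IntegerVector deme,
                             int n_demes) {
  const int n = alleles.nrow(), L = alleles.ncol(), D = n_demes;
  const int n_pairs = D * (D - 1) / 2;
  NumericVector out(4 * D + 4 * n_pairs, 0.0);

  // single-deme statistics
  for (int d = 0; d < D; ++d) {
    double s_nal = 0, s_he = 0, s_var = 0, s_mgw = 0;
    int nl = 0;
    for (int l = 0; l < L; ++l) {
      std::vector<int> a;
      for (int i = 0; i < n; ++i)
        if (deme[i] == d && alleles(i, l) != NA_INTEGER)
          a.push_back(alleles(i, l));
      const int m = (int) a.size();
      if (m < 2) continue;
      ++nl;
      std::sort(a.begin(), a.end());
      int k = 1, amin = a[0], amax = a[m - 1];
      double sum = a[0], sq = 0.0, hom = 0.0;
      for (int i = 1; i < m; ++i) { if (a[i] != a[i - 1]) ++k; sum += a[i]; }
      const double mean = sum / m;
      int run = 1;
      for (int i = 1; i <= m; ++i) {
        if (i < m && a[i] == a[i - 1]) { ++run; continue; }
        const double p = (double) run / m;
        hom += p * p;
        run = 1;
      }
      for (int i = 0; i < m; ++i) sq += (a[i] - mean) * (a[i] - mean);
      s_nal += k;
      s_he += (double) m / (m - 1) * (1.0 - hom);
      s_var += sq / (m - 1);
      s_mgw += (double) k / (amax - amin + 1);
    }
    if (nl == 0) nl = 1;
    out[4 * d + 0] = s_nal / nl;
    out[4 * d + 1] = s_he / nl;
    out[4 * d + 2] = s_var / nl;
    out[4 * d + 3] = s_mgw / nl;
  }

  // pair statistics
  int pp = 0;
  for (int d1 = 0; d1 < D; ++d1) for (int d2 = d1 + 1; d2 < D; ++d2, ++pp) {
    double th_num = 0, th_den = 0, s_hep = 0, s_dmu = 0, s_das = 0;
    int nl = 0;
    for (int l = 0; l < L; ++l) {
      std::vector<int> a1, a2;
      for (int i = 0; i < n; ++i) {
        if (alleles(i, l) == NA_INTEGER) continue;
        if (deme[i] == d1) a1.push_back(alleles(i, l));
        else if (deme[i] == d2) a2.push_back(alleles(i, l));
      }
      const int n1 = (int) a1.size(), n2 = (int) a2.size();
      if (n1 < 2 || n2 < 2) continue;
      ++nl;
      const double nn = n1 + n2;
      const double nc = (nn - (double) (n1 * (double) n1 + n2 * (double) n2) / nn);
      // distinct alleles of the pooled pair
      std::vector<int> all(a1);
      all.insert(all.end(), a2.begin(), a2.end());
      std::sort(all.begin(), all.end());
      all.erase(std::unique(all.begin(), all.end()), all.end());
      double hom_pool = 0.0, m1 = 0.0, m2 = 0.0, das = 0.0;
      for (size_t u = 0; u < all.size(); ++u) {
        const int al = all[u];
        int c1 = 0, c2 = 0;
        for (int i = 0; i < n1; ++i) if (a1[i] == al) ++c1;
        for (int i = 0; i < n2; ++i) if (a2[i] == al) ++c2;
        const double p1 = (double) c1 / n1, p2 = (double) c2 / n2;
        const double pb = (c1 + c2) / nn;
        hom_pool += pb * pb;
        das += std::min(p1, p2);
        // WC haploid components, r = 2 demes
        const double msp = n1 * (p1 - pb) * (p1 - pb) + n2 * (p2 - pb) * (p2 - pb);
        const double msg = (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nn - 2.0);
        th_num += msp - msg;
        th_den += msp + (nc - 1.0) * msg;
      }
      for (int i = 0; i < n1; ++i) m1 += a1[i];
      for (int i = 0; i < n2; ++i) m2 += a2[i];
      m1 /= n1; m2 /= n2;
      s_hep += nn / (nn - 1.0) * (1.0 - hom_pool);
      s_dmu += (m1 - m2) * (m1 - m2);
      s_das += 1.0 - das;
    }
    if (nl == 0) nl = 1;
    const int off = 4 * D + 4 * pp;
    out[off + 0] = (th_den != 0.0) ? th_num / th_den : 0.0;
    out[off + 1] = s_hep / nl;
    out[off + 2] = s_dmu / nl;
    out[off + 3] = s_das / nl;
  }
  return out;
}
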