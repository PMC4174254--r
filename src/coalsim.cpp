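// Structured-coalescent simulator for a serial-founder model of six
// continental regions (Africa, Oceania, Europe, Central Asia, East Asia,
// America) with no post-divergence migration. Time runs backwards in
// generations. Each terminal regional branch grows exponentially from its
// founding size to its current size; backbone (ancestral non-African)
// branches are constant at the out-of-Africa founder size; beyond the root
// time the ancestral African population is constant.
//
// All random numbers come from R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int N_DEME = 6;
static const int N_EPOCH = 7;

// Deme indices: 0 Africa, 1 Oceania, 2 Europe, 3 Central Asia,
// 4 East Asia, 5 America.
// Epoch e spans [bounds[e], bounds[e+1]) with
// bounds = {0, T6, T5, T4, T3, T2, T1, +Inf}.
// At the end of epoch e (e = 0..4) deme merges[e] empties into the next
// backbone host: 5->4 (T6), 4->3 (T5), 3->2 (T4), 2->1 (T3), 1->0 (T2).

struct Plan {
  double bounds[N_EPOCH + 1];
  int rtype[N_EPOCH][N_DEME];     // 0 inactive, 1 constant, 2 exponential
  double rpar1[N_EPOCH][N_DEME];  // N (constant) or N_cur (exponential)
  double rpar2[N_EPOCH][N_DEME];  // growth coefficient beta (exponential)
  int merge_src[N_EPOCH];
  int merge_dst[N_EPOCH];
};

// times_gen: T1..T6 in generations (T1 > T2 > ... > T6 > 0).
// sizes: N_anc_africa, N_ooa, N_anc[Oceania,Europe,CentralAsia,EastAsia,
//        America], N_cur[Africa,Oceania,Europe,CentralAsia,EastAsia,America]
//        (13 haploid effective sizes of the transmitting sex).
static void build_plan(const double *times_gen, const double *sizes,
                       Plan &pl) {
  const double T1 = times_gen[0], T2 = times_gen[1], T3 = times_gen[2],
               T4 = times_gen[3], T5 = times_gen[4], T6 = times_gen[5];
  const double n_anc_afr = sizes[0], n_ooa = sizes[1];
  const double n_anc[N_DEME] = {n_anc_afr, sizes[2], sizes[3], sizes[4],
                                sizes[5], sizes[6]};
  const double n_cur[N_DEME] = {sizes[7], sizes[8], sizes[9], sizes[10],
                                sizes[11], sizes[12]};
  const double t_found[N_DEME] = {T1, T3, T4, T5, T5, T6};

  pl.bounds[0] = 0.0; pl.bounds[1] = T6; pl.bounds[2] = T5;
  pl.bounds[3] = T4; pl.bounds[4] = T3; pl.bounds[5] = T2;
  pl.bounds[6] = T1; pl.bounds[7] = R_PosInf;

  // last epoch in which each deme still holds its own (terminal) lineage
  // pool, counted in epoch indices; afterwards it either hosts a backbone
  // or is merged away.
  for (int e = 0; e < N_EPOCH; ++e)
    for (int d = 0; d < N_DEME; ++d) pl.rtype[e][d] = 0;

  for (int d = 0; d < N_DEME; ++d) {
    double beta = std::log(n_anc[d] / n_cur[d]) / t_found[d];
    for (int e = 0; e < N_EPOCH; ++e) {
      double t0 = pl.bounds[e];
      if (t0 >= t_found[d]) break;  // terminal branch ends at founding
      pl.rtype[e][d] = 2;
      pl.rpar1[e][d] = n_cur[d];
      pl.rpar2[e][d] = beta;
    }
  }
  // backbone hosts: Oceania slot holds the out-of-Africa pool in [T3,T2),
  // Europe slot the Eurasian pool in [T4,T3), Central Asia slot the Asian
  // pool in [T5,T4); all constant at the OOA founder size.
  pl.rtype[4][1] = 1; pl.rpar1[4][1] = n_ooa;  // [T3,T2)
  pl.rtype[3][2] = 1; pl.rpar1[3][2] = n_ooa;  // [T4,T3)
  pl.rtype[2][3] = 1; pl.rpar1[2][3] = n_ooa;  // [T5,T4)
  // ancestral Africa beyond T1
  pl.rtype[6][0] = 1; pl.rpar1[6][0] = n_anc_afr;

  pl.merge_src[0] = 5; pl.merge_dst[0] = 4;
  pl.merge_src[1] = 4; pl.merge_dst[1] = 3;
  pl.merge_src[2] = 3; pl.merge_dst[2] = 2;
  pl.merge_src[3] = 2; pl.merge_dst[3] = 1;
  pl.merge_src[4] = 1; pl.merge_dst[4] = 0;
  pl.merge_src[5] = -1; pl.merge_dst[5] = -1;
  pl.merge_src[6] = -1; pl.merge_dst[6] = -1;
}

// Simulate one genealogy. parent/node_time must have length 2n-1.
// Returns number of nodes created. Leaves are nodes 0..n-1 ordered by deme.
static int sim_tree(const Plan &pl, const int *nsam,
                    std::vector<int> &parent, std::vector<double> &node_time,
                    std::vector<int> &leaf_deme) {
  int n = 0;
  for (int d = 0; d < N_DEME; ++d) n += nsam[d];
  int n_nodes = 2 * n - 1;
  std::vector<std::vector<int> > act(N_DEME);
  int leaf = 0;
  for (int d = 0; d < N_DEME; ++d) {
    act[d].reserve(n);
    for (int i = 0; i < nsam[d]; ++i) {
      act[d].push_back(leaf);
      leaf_deme[leaf] = d;
      parent[leaf] = -1;
      node_time[leaf] = 0.0;
      ++leaf;
    }
  }
  if (n == 1) return 1;
  int next_node = n;
  int total_act = n;
  for (int e = 0; e < N_EPOCH && total_act > 1; ++e) {
    double t1 = pl.bounds[e + 1];
    for (int d = 0; d < N_DEME; ++d) {
      std::vector<int> &L = act[d];
      if (L.size() < 2) continue;
      double t = pl.bounds[e];
      while (L.size() >= 2) {
        double k = (double)L.size();
        double C = k * (k - 1.0) / 2.0;
        double u = exp_rand();
        double tn;
        if (pl.rtype[e][d] == 1) {
          tn = t + u * pl.rpar1[e][d] / C;
        } else {
          double Nc = pl.rpar1[e][d], b = pl.rpar2[e][d];
          if (b == 0.0) {
            tn = t + u * Nc / C;
          } else {
            // invert the integrated coalescence intensity of
            // N(t) = Nc * exp(b t)
            double rhs = std::exp(-b * t) - u * Nc * b / C;
            tn = (rhs <= 0.0) ? R_PosInf : (-std::log(rhs) / b);
          }
        }
        if (tn >= t1) break;
        int ksz = (int)L.size();
        int i = (int)(unif_rand() * ksz); if (i >= ksz) i = ksz - 1;
        int j = (int)(unif_rand() * (ksz - 1)); if (j >= ksz - 1) j = ksz - 2;
        if (j >= i) ++j;
        int a = L[i], b2 = L[j];
        int v = next_node++;
        parent[a] = v; parent[b2] = v;
        parent[v] = -1; node_time[v] = tn;
        // replace i with v, remove j (order within the pool is irrelevant)
        L[i] = v;
        L[j] = L.back(); L.pop_back();
        --total_act;
        t = tn;
      }
    }
    int s = pl.merge_src[e];
    if (s >= 0 && !act[s].empty()) {
      std::vector<int> &D = act[pl.merge_dst[e]];
      D.insert(D.end(), act[s].begin(), act[s].end());
      act[s].clear();
    }
  }
  return n_nodes;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(NumericVector times_gen, NumericVector sizes,
                       IntegerVector nsam) {
  Plan pl;
  build_plan(REAL(times_gen), REAL(sizes), pl);
  int n = 0, ns[N_DEME];
  for (int d = 0; d < N_DEME; ++d) { ns[d] = nsam[d]; n += ns[d]; }
  int n_nodes = (n == 1) ? 1 : 2 * n - 1;
  std::vector<int> parent(n_nodes), leaf_deme(n);
  std::vector<double> node_time(n_nodes);
  sim_tree(pl, ns, parent, node_time, leaf_deme);
  return List::create(
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
    _["leaf_deme"] = IntegerVector(leaf_deme.begin(), leaf_deme.end()),
    _["n_leaves"] = n);
}

// Accumulate per-region sufficient statistics for summary statistics:
// S[r]   total mutations on branches polymorphic within region r,
// W[r]   sum over within-region pairs of pairwise differences,
// B[rs]  sum over between-region pairs of pairwise differences,
// for Poisson(branch length * mu_gen) infinite-sites mutations.
// Output vector: S[0..5], W[0..5], B[(0,1),(0,2),...,(4,5)] = 27 values.
static void raw_stats_one(const Plan &pl, const int *nsam, double mu_gen,
                          std::vector<int> &parent,
                          std::vector<double> &node_time,
                          std::vector<int> &leaf_deme,
                          std::vector<int> &cnt, std::vector<int> &ord,
                          double *out) {
  int n = 0;
  for (int d = 0; d < N_DEME; ++d) n += nsam[d];
  int n_nodes = 2 * n - 1;
  sim_tree(pl, nsam, parent, node_time, leaf_deme);
  // leaf counts per region below each node; parents always have larger
  // times than children, so a time-ordered pass accumulates correctly.
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int v = 0; v < n; ++v) cnt[v * N_DEME + leaf_deme[v]] = 1;
  for (int v = 0; v < n_nodes; ++v) ord[v] = v;
  std::sort(ord.begin(), ord.begin() + n_nodes,
            [&node_time](int a, int b) { return node_time[a] < node_time[b]; });
  for (int ii = 0; ii < n_nodes; ++ii) {
    int v = ord[ii];
    int p = parent[v];
    if (p < 0) continue;
    for (int d = 0; d < N_DEME; ++d)
      cnt[p * N_DEME + d] += cnt[v * N_DEME + d];
  }
  for (int i = 0; i < 27; ++i) out[i] = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    int p = parent[v];
    if (p < 0) continue;
    double len = node_time[p] - node_time[v];
    if (len <= 0.0) continue;
    double m = R::rpois(len * mu_gen);
    if (m <= 0.0) continue;
    const int *c = &cnt[v * N_DEME];
    int bi = 12;
    for (int r = 0; r < N_DEME; ++r) {
      int cr = c[r], nr = nsam[r];
      if (cr > 0 && cr < nr) out[r] += m;             // S_r
      out[6 + r] += m * (double)cr * (nr - cr);        // W_r
      for (int s = r + 1; s < N_DEME; ++s) {
        int cs = c[s], nss = nsam[s];
        out[bi + (s - r - 1)] +=
          m * ((double)cr * (nss - cs) + (double)cs * (nr - cr));
      }
      bi += (N_DEME - r - 1);
    }
  }
}

// Batch simulator: one row of raw statistics per parameter row.
// params: n_sims x 19 matrix, columns T1..T6 (generations) then the 13
// sizes in build_plan order. mu_gen: expected mutations per generation of
// branch length (locus length x per-site-per-year rate x generation time).
// [[Rcpp::export]]
NumericMatrix sim_raw_batch_cpp(NumericMatrix params, IntegerVector nsam,
                                double mu_gen) {
  int n_sims = params.nrow();
  if (params.ncol() != 19) stop("params must have 19 columns");
  int n = 0, ns[N_DEME];
  for (int d = 0; d < N_DEME; ++d) { ns[d] = nsam[d]; n += ns[d]; }
  if (n < 2) stop("need at least two samples in total");
  int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes), leaf_deme(n), ord(n_nodes);
  std::vector<double> node_time(n_nodes);
  std::vector<int> cnt(n_nodes * N_DEME);
  NumericMatrix out(n_sims, 27);
  Plan pl;
  double tg[6], sz[13], buf[27];
  for (int i = 0; i < n_sims; ++i) {
    for (int j = 0; j < 6; ++j) tg[j] = params(i, j);
    for (int j = 0; j < 13; ++j) sz[j] = params(i, 6 + j);
    build_plan(tg, sz, pl);
    raw_stats_one(pl, ns, mu_gen, parent, node_time, leaf_deme, cnt, ord,
                  buf);
    for (int j = 0; j < 27; ++j) out(i, j) = buf[j];
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
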