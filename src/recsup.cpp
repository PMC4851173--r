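// Core kernels: rooted/unrooted tree structures, LCA-mapping reconciliation
// distances (duplications, losses, deep coalescences) minimized over all
// gene-tree rootings, the mulRF distance on multi-labeled trees, and the
// multiple-try Metropolis sampler over (species tree, gene trees, penalties).
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <array>
#include <vector>
#include <string>
#include <cstring>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rooted binary tree: leaves 0..nl-1 (leaf id == species id in the tree's own
// label domain), internal nodes nl..2nl-2; root is any internal id.
// ---------------------------------------------------------------------------
struct RTree {
  int nl = 0;
  std::vector<int> par, lch, rch, dep;
  int root = -1;
  int nn() const { return nl <= 1 ? nl : 2 * nl - 1; }
  void rebuild() {
    int n = nn();
    lch.assign(n, -1); rch.assign(n, -1); dep.assign(n, 0);
    root = -1;
    for (int v = 0; v < n; ++v) {
      int p = par[v];
      if (p < 0) { root = v; continue; }
      if (lch[p] < 0) lch[p] = v; else rch[p] = v;
    }
    std::vector<int> st{root};
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      if (v >= nl) {
        dep[lch[v]] = dep[v] + 1; st.push_back(lch[v]);
        dep[rch[v]] = dep[v] + 1; st.push_back(rch[v]);
      }
    }
  }
  int lca(int a, int b) const {
    while (a != b) {
      if (dep[a] < dep[b]) b = par[b]; else a = par[a];
    }
    return a;
  }
  // full LCA lookup table; worthwhile because species trees are small and
  // each restricted tree is queried millions of times
  std::vector<int> lcatab;
  void build_lca() {
    int n = nn();
    lcatab.assign((size_t)n * n, 0);
    for (int a = 0; a < n; ++a)
      for (int b = a; b < n; ++b)
        lcatab[(size_t)a * n + b] = lcatab[(size_t)b * n + a] = lca(a, b);
  }
  inline int lcaq(int a, int b) const { return lcatab[(size_t)a * nn() + b]; }
};

static uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// label-aware canonical hash of a rooted topology (child order ignored)
static uint64_t rtree_hash_node(const RTree& S, int v) {
  if (v < S.nl) return mix64((uint64_t)v + 1);
  uint64_t a = rtree_hash_node(S, S.lch[v]);
  uint64_t b = rtree_hash_node(S, S.rch[v]);
  if (a > b) std::swap(a, b);
  return mix64(a * 3ULL + mix64(b + 0x51ULL));
}
static uint64_t rtree_hash(const RTree& S) { return rtree_hash_node(S, S.root); }

// Induced subtree of S on a subset of leaves (keep[] over old leaf ids).
// New leaf ids follow the order of `kept` (ascending old ids).
static RTree restrict_rtree(const RTree& S, const std::vector<int>& kept) {
  int k = (int)kept.size();
  RTree R; R.nl = k;
  if (k == 1) { R.par.assign(1, -1); R.lch.assign(1, -1); R.rch.assign(1, -1);
    R.dep.assign(1, 0); R.root = 0; return R; }
  std::vector<int> newleaf(S.nl, -1);
  for (int i = 0; i < k; ++i) newleaf[kept[i]] = i;
  R.par.assign(2 * k - 1, -1);
  int next = k;
  std::vector<std::pair<int,std::pair<int,int>>> ints;
  // iterative postorder reduce
  std::vector<int> res(S.nn(), -1);
  std::vector<int> order; order.reserve(S.nn());
  std::vector<int> st{S.root};
  while (!st.empty()) { int v = st.back(); st.pop_back(); order.push_back(v);
    if (v >= S.nl) { st.push_back(S.lch[v]); st.push_back(S.rch[v]); } }
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    if (v < S.nl) { res[v] = newleaf[v]; continue; }
    int a = res[S.lch[v]], b = res[S.rch[v]];
    if (a < 0) res[v] = b;
    else if (b < 0) res[v] = a;
    else { int id = next++; ints.push_back({id, {a, b}}); res[v] = id; }
  }
  for (auto& e : ints) { R.par[e.second.first] = e.first; R.par[e.second.second] = e.first; }
  R.rebuild();
  return R;
}

// ---------------------------------------------------------------------------
// Unrooted binary topology: leaves 0..nl-1 with a species id per leaf,
// internal nodes nl..2nl-3, edges in a fixed order (ties over rootings are
// broken by the smallest edge index).
// ---------------------------------------------------------------------------
struct UTree {
  int nl = 0;
  std::vector<int> spp;          // species id per leaf (local, family domain)
  std::vector<int> e1, e2;       // edge endpoints
  std::vector<std::vector<std::pair<int,int>>> adj;  // node -> (edge, other end)
  // flat orientation anchored at leaf 0, precomputed for the rerooting DP
  std::vector<int> o_order, o_par, o_pedge;
  std::vector<std::array<int,2>> o_kids;
  int nn() const { return nl <= 2 ? nl : 2 * nl - 2; }
  int ne() const { return (int)e1.size(); }
  void build_adj() {
    adj.assign(nn(), {});
    for (int e = 0; e < ne(); ++e) {
      adj[e1[e]].push_back({e, e2[e]});
      adj[e2[e]].push_back({e, e1[e]});
    }
  }
  void build_orient() {
    int n = nn();
    if (nl < 3) return;
    o_par.assign(n, -1); o_pedge.assign(n, -1);
    o_kids.assign(n, {-1, -1});
    o_order.clear(); o_order.reserve(n);
    std::vector<std::pair<int,int>> st{{0, -1}};
    while (!st.empty()) {
      auto [v, from] = st.back(); st.pop_back();
      o_order.push_back(v);
      for (auto& [e, w] : adj[v]) if (w != from) {
        o_par[w] = v; o_pedge[w] = e; st.push_back({w, v});
      }
    }
    for (int v : o_order) if (v != 0) {
      auto& k = o_kids[o_par[v]];
      if (k[0] < 0) k[0] = v; else k[1] = v;
    }
  }
};

static UTree utree_from_edges(const IntegerMatrix& edges, const IntegerVector& spp) {
  UTree G; G.nl = spp.size();
  G.spp.assign(spp.begin(), spp.end());
  for (int i = 0; i < edges.nrow(); ++i) { G.e1.push_back(edges(i, 0)); G.e2.push_back(edges(i, 1)); }
  G.build_adj();
  return G;
}

// Canonical key of one split given per-species copy counts on one side.
// `side` and `total` are counts per local species; key is the lexicographic
// min of side and complement, serialized as bytes.
static std::string split_key(const std::vector<int>& side, const std::vector<int>& total) {
  int ns = (int)side.size();
  std::string a(ns, '\0'), b(ns, '\0');
  for (int i = 0; i < ns; ++i) { a[i] = (char)side[i]; b[i] = (char)(total[i] - side[i]); }
  return a <= b ? a : b;
}

// Nontrivial splits of an unrooted multree as species-count multisets (sorted).
static std::vector<std::string> utree_splits(const UTree& G, int nsp) {
  std::vector<std::string> out;
  if (G.nl < 4) return out;
  std::vector<int> total(nsp, 0);
  for (int l = 0; l < G.nl; ++l) total[G.spp[l]]++;
  for (int e = 0; e < G.ne(); ++e) {
    if (G.e1[e] < G.nl || G.e2[e] < G.nl) continue;  // pendant edge: trivial
    // leaves on the e1 side
    std::vector<int> side(nsp, 0);
    int cnt = 0;
    std::vector<std::pair<int,int>> st{{G.e1[e], G.e2[e]}};
    while (!st.empty()) {
      auto [v, from] = st.back(); st.pop_back();
      if (v < G.nl) { side[G.spp[v]]++; cnt++; continue; }
      for (auto& [ee, w] : G.adj[v]) if (w != from) st.push_back({w, v});
    }
    if (cnt < 2 || G.nl - cnt < 2) continue;
    out.push_back(split_key(side, total));
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Nontrivial splits of the extended species tree: S restricted to the family
// species, with each species holding k>1 gene copies read as a k-furcation of
// copy leaves.  Enumerates edges of the unrooted version (one root-child is
// skipped to avoid the duplicated root split).
static std::vector<std::string> extended_splits(const RTree& S, const std::vector<int>& copies) {
  int nsp = S.nl;
  std::vector<std::string> out;
  std::vector<int> total(copies);
  int tot = 0; for (int c : copies) tot += c;
  if (nsp < 2) return out;
  // subtree copy counts
  std::vector<std::vector<int>> cc(S.nn());
  std::vector<int> order, st{S.root};
  while (!st.empty()) { int v = st.back(); st.pop_back(); order.push_back(v);
    if (v >= S.nl) { st.push_back(S.lch[v]); st.push_back(S.rch[v]); } }
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    cc[v].assign(nsp, 0);
    if (v < S.nl) cc[v][v] = copies[v];
    else for (int j = 0; j < nsp; ++j) cc[v][j] = cc[S.lch[v]][j] + cc[S.rch[v]][j];
  }
  int skip = (S.root >= S.nl) ? S.rch[S.root] : -1;
  for (int v = 0; v < S.nn(); ++v) {
    if (v == S.root || v == skip) continue;
    int side = 0; for (int j = 0; j < nsp; ++j) side += cc[v][j];
    if (side < 2 || tot - side < 2) continue;
    out.push_back(split_key(cc[v], total));
  }
  std::sort(out.begin(), out.end());
  return out;
}

static int multiset_symdiff(const std::vector<std::string>& a, const std::vector<std::string>& b) {
  size_t i = 0, j = 0; int d = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++i; ++j; }
    else if (a[i] < b[j]) { ++d; ++i; }
    else { ++d; ++j; }
  }
  d += (int)(a.size() - i) + (int)(b.size() - j);
  return d;
}

// ---------------------------------------------------------------------------
// Reconciliation distances for one rooting, and the minimum over rootings.
// ---------------------------------------------------------------------------
struct DistCtx {                 // scratch reused across rootings
  std::vector<int> M;            // LCA map per gene node (+1 slot for root)
  std::vector<int> cnt;          // lineages crossing the top of each S branch
  std::vector<int> order, ofrom; // DFS order
  std::vector<int> par, pedge;   // rerooting-DP scratch
  std::vector<std::array<int,2>> kids;
  struct UD { int M; long dup, loss, ils; };
  std::vector<UD> down, up;
};

struct RootCost { long dups, losses, ils; };

// Evaluate the rooting of G on edge e against restricted species tree S.
static RootCost eval_rooting(const UTree& G, const RTree& S, int e, DistCtx& cx) {
  int n = G.nn();
  cx.M.assign(n + 1, -1);
  cx.cnt.assign(S.nn(), 0);
  cx.order.clear(); cx.ofrom.clear();
  // DFS from both endpoints of e, avoiding e
  std::vector<std::pair<int,int>> st;
  st.push_back({G.e1[e], -1}); st.push_back({G.e2[e], -1});
  while (!st.empty()) {
    auto [v, from] = st.back(); st.pop_back();
    cx.order.push_back(v); cx.ofrom.push_back(from);
    for (auto& [ee, w] : G.adj[v]) if (ee != e && w != from) st.push_back({w, v});
  }
  long dups = 0, losses = 0;
  // postorder: children before parents
  for (int i = (int)cx.order.size() - 1; i >= 0; --i) {
    int v = cx.order[i];
    if (v < G.nl) { cx.M[v] = G.spp[v]; continue; }
    int c1 = -1, c2 = -1, from = cx.ofrom[i];
    for (auto& [ee, w] : G.adj[v]) {
      if (w == from || ee == e) continue;
      if (c1 < 0) c1 = w; else c2 = w;
    }
    int Ma = cx.M[c1], Mb = cx.M[c2];
    int Mv = S.lca(Ma, Mb);
    cx.M[v] = Mv;
    bool dup = (Mv == Ma || Mv == Mb);
    if (dup) dups++;
    int spec = dup ? 0 : 1;
    losses += (S.dep[Ma] - S.dep[Mv] - spec) + (S.dep[Mb] - S.dep[Mv] - spec);
    // deep coalescence bookkeeping: lineage child -> v crosses species
    // branches from M(child) up to (excl.) M(v)
    for (int Mc : {Ma, Mb})
      for (int s = Mc; s != Mv; s = S.par[s]) cx.cnt[s]++;
  }
  // virtual root: children are the two endpoints of e
  {
    int a = G.e1[e], b = G.e2[e];
    int Ma = cx.M[a], Mb = cx.M[b];
    int Mv = S.lca(Ma, Mb);
    bool dup = (Mv == Ma || Mv == Mb);
    if (dup) dups++;
    int spec = dup ? 0 : 1;
    losses += (S.dep[Ma] - S.dep[Mv] - spec) + (S.dep[Mb] - S.dep[Mv] - spec);
    for (int Mc : {Ma, Mb})
      for (int s = Mc; s != Mv; s = S.par[s]) cx.cnt[s]++;
    // lineage above the virtual root reaches the species root
    for (int s = Mv; s != S.root; s = S.par[s]) cx.cnt[s]++;
  }
  long ils = 0;
  for (int s = 0; s < S.nn(); ++s)
    if (s != S.root && cx.cnt[s] > 1) ils += cx.cnt[s] - 1;
  return {dups, losses, ils};
}

struct DV { double d[4]; int rstar, rstar2; };

// Linear-time evaluation of all rootings: every cost (duplications, losses,
// deep coalescences) is a sum of local node terms of the LCA images, so a
// down/up rerooting sweep gives the per-edge totals in O(n) LCA queries.
// Deep coalescences use the identity
//   ILS = sum over gene edges of pathlen(M(child), M(parent))
//         + pathlen(M(root), S.root) - (#branches of S).
static inline void node_terms(const RTree& S, int Ma, int Mb, int Mg,
                              long& dup, long& loss, long& ils) {
  bool d = (Mg == Ma || Mg == Mb);
  int spec = d ? 0 : 1;
  if (d) dup += 1;
  loss += (S.dep[Ma] - S.dep[Mg] - spec) + (S.dep[Mb] - S.dep[Mg] - spec);
  ils += (S.dep[Ma] - S.dep[Mg]) + (S.dep[Mb] - S.dep[Mg]);
}

static void min_roots_fast(UTree& G, const RTree& S0, DistCtx& cx,
                           long& bd, long& bl, long& bi, int& rstar, int& rstar2) {
  RTree& S = const_cast<RTree&>(S0);
  if (S.lcatab.empty()) S.build_lca();
  int n = G.nn();
  if (G.o_order.empty()) G.build_orient();
  const auto& par = G.o_par;
  const auto& pedge = G.o_pedge;
  const auto& order = G.o_order;
  const auto& kids = G.o_kids;
  cx.down.assign(n, {});
  cx.up.assign(n, {});
  auto& down = cx.down; auto& up = cx.up;
  // postorder: down[v] = subtree below v's parent edge
  for (int i = n - 1; i >= 0; --i) {
    int v = order[i];
    if (v == 0) continue;
    if (v < G.nl) { down[v] = {G.spp[v], 0, 0, 0}; continue; }
    int a = kids[v][0], b = kids[v][1];
    DistCtx::UD r{S.lcaq(down[a].M, down[b].M),
             down[a].dup + down[b].dup, down[a].loss + down[b].loss,
             down[a].ils + down[b].ils};
    node_terms(S, down[a].M, down[b].M, r.M, r.dup, r.loss, r.ils);
    down[v] = r;
  }
  // preorder: up[v] = complement of v's parent edge
  for (int v : order) {
    if (v == 0) continue;
    int u = par[v];
    if (u == 0) { up[v] = {G.spp[0], 0, 0, 0}; continue; }
    int s = (kids[u][0] == v) ? kids[u][1] : kids[u][0];
    DistCtx::UD r{S.lcaq(down[s].M, up[u].M),
             down[s].dup + up[u].dup, down[s].loss + up[u].loss,
             down[s].ils + up[u].ils};
    node_terms(S, down[s].M, up[u].M, r.M, r.dup, r.loss, r.ils);
    up[v] = r;
  }
  long nbranch = S.nn() - 1;
  bd = -1; bl = -1; bi = -1; rstar = 0; rstar2 = 0;
  long bestdl = -1;
  for (int e = 0; e < G.ne(); ++e) {
    // the endpoint whose parent edge is e
    int v = (pedge[G.e1[e]] == e) ? G.e1[e] : G.e2[e];
    long dup = down[v].dup + up[v].dup;
    long loss = down[v].loss + up[v].loss;
    long ils = down[v].ils + up[v].ils;
    int Mr = S.lcaq(down[v].M, up[v].M);
    node_terms(S, down[v].M, up[v].M, Mr, dup, loss, ils);
    ils += S.dep[Mr] - nbranch;
    if (bestdl < 0 || dup + loss < bestdl) { bestdl = dup + loss; bd = dup; bl = loss; rstar = e; }
    if (bi < 0 || ils < bi) { bi = ils; rstar2 = e; }
  }
}

// d1..d3 minimized over rootings (d1,d2 jointly at r*, d3 at r**); d4 = mulRF.
// S must already be restricted to the family's species; leaf ids match spp.
static DV distvec(UTree& G, const RTree& S, bool use_mulrf,
                  const std::vector<std::string>* gsplits, DistCtx& cx,
                  const std::vector<std::string>* esplits = nullptr) {
  DV out; out.d[0] = out.d[1] = out.d[2] = out.d[3] = 0;
  out.rstar = 0; out.rstar2 = 0;
  if (G.nl >= 2) {
    long bestdl = -1, bestils = -1; long bd = 0, bl = 0;
    if (G.nl == 2) {
      // single cherry: treat the unique edge as the rooting
      int Ma = G.spp[0], Mb = G.spp[1];
      int Mv = S.lca(Ma, Mb);
      bool dup = (Mv == Ma || Mv == Mb);
      int spec = dup ? 0 : 1;
      bd = dup ? 1 : 0;
      bl = (S.dep[Ma] - S.dep[Mv] - spec) + (S.dep[Mb] - S.dep[Mv] - spec);
      cx.cnt.assign(S.nn(), 0);
      for (int Mc : {Ma, Mb}) for (int s = Mc; s != Mv; s = S.par[s]) cx.cnt[s]++;
      for (int s = Mv; s != S.root; s = S.par[s]) cx.cnt[s]++;
      long ils = 0;
      for (int s = 0; s < S.nn(); ++s) if (s != S.root && cx.cnt[s] > 1) ils += cx.cnt[s] - 1;
      bestdl = bd + bl; bestils = ils;
      out.d[0] = bd; out.d[1] = bl; out.d[2] = ils;
      (void)bestdl; (void)bestils;
    } else {
      long d0, l0, i0;
      min_roots_fast(G, S, cx, d0, l0, i0, out.rstar, out.rstar2);
      out.d[0] = d0; out.d[1] = l0; out.d[2] = i0;
    }
  }
  if (use_mulrf) {
    const std::vector<std::string>* es = esplits;
    std::vector<std::string> tmp;
    if (!es) {
      std::vector<int> copies(S.nl, 0);
      for (int l = 0; l < G.nl; ++l) copies[G.spp[l]]++;
      tmp = extended_splits(S, copies);
      es = &tmp;
    }
    if (gsplits) out.d[3] = multiset_symdiff(*gsplits, *es);
    else {
      std::vector<std::string> gs = utree_splits(G, S.nl);
      out.d[3] = multiset_symdiff(gs, *es);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// R-facing kernels
// ---------------------------------------------------------------------------

// Species parent vector (0-based, -1 at root) -> RTree
static RTree rtree_from_parent(const IntegerVector& par) {
  RTree S; S.nl = (par.size() + 1) / 2;
  S.par.assign(par.begin(), par.end());
  S.rebuild();
  return S;
}

// [[Rcpp::export]]
List cpp_distvec(IntegerVector s_parent, IntegerMatrix g_edges, IntegerVector g_spp,
                 bool mulrf) {
  RTree S = rtree_from_parent(s_parent);
  UTree G = utree_from_edges(g_edges, g_spp);
  DistCtx cx;
  DV dv = distvec(G, S, mulrf, nullptr, cx);
  return List::create(_["dups"] = dv.d[0], _["losses"] = dv.d[1],
                      _["ils"] = dv.d[2], _["mulrf"] = dv.d[3],
                      _["r_star"] = dv.rstar + 1, _["r_star2"] = dv.rstar2 + 1);
}

// per-rooting costs, used by the brute-force oracle comparisons
// [[Rcpp::export]]
IntegerMatrix cpp_rooting_costs(IntegerVector s_parent, IntegerMatrix g_edges,
                                IntegerVector g_spp) {
  RTree S = rtree_from_parent(s_parent);
  UTree G = utree_from_edges(g_edges, g_spp);
  DistCtx cx;
  IntegerMatrix out(G.ne(), 3);
  for (int e = 0; e < G.ne(); ++e) {
    RootCost rc = eval_rooting(G, S, e, cx);
    out(e, 0) = (int)rc.dups; out(e, 1) = (int)rc.losses; out(e, 2) = (int)rc.ils;
  }
  return out;
}

// empirical maxima of losses and deep coalescences of every topology of one
// family against a set of reference species trees (backs the m scaling)
// [[Rcpp::export]]
NumericVector cpp_scaling_maxes(List edges_list, IntegerVector g_spp,
                                List ref_parents) {
  double mloss = 0, mils = 0;
  DistCtx cx;
  std::vector<UTree> topos;
  for (int t = 0; t < edges_list.size(); ++t)
    topos.push_back(utree_from_edges(edges_list[t], g_spp));
  for (int r = 0; r < ref_parents.size(); ++r) {
    RTree S = rtree_from_parent(ref_parents[r]);
    for (auto& G : topos) {
      DV dv = distvec(G, S, false, nullptr, cx);
      if (dv.d[1] > mloss) mloss = dv.d[1];
      if (dv.d[2] > mils) mils = dv.d[2];
    }
  }
  return NumericVector::create(mloss, mils);
}

// ---------------------------------------------------------------------------
// RNG helpers on R's stream
// ---------------------------------------------------------------------------
static int rint(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}
static int sample_logw(const std::vector<double>& lw) {
  double mx = lw[0];
  for (double x : lw) if (x > mx) mx = x;
  double tot = 0;
  std::vector<double> p(lw.size());
  for (size_t i = 0; i < lw.size(); ++i) { p[i] = std::exp(lw[i] - mx); tot += p[i]; }
  double u = unif_rand() * tot, c = 0;
  for (size_t i = 0; i < lw.size(); ++i) { c += p[i]; if (u <= c) return (int)i; }
  return (int)lw.size() - 1;
}
static double logsumexp(const std::vector<double>& lw) {
  double mx = lw[0];
  for (double x : lw) if (x > mx) mx = x;
  double s = 0;
  for (double x : lw) s += std::exp(x - mx);
  return mx + std::log(s);
}

// ---------------------------------------------------------------------------
// Species tree proposals (all symmetric; see package vignette)
// ---------------------------------------------------------------------------
static void subtree_mark(const RTree& S, int v, std::vector<char>& mark) {
  std::vector<int> st{v};
  while (!st.empty()) {
    int x = st.back(); st.pop_back();
    mark[x] = 1;
    if (x >= S.nl) { st.push_back(S.lch[x]); st.push_back(S.rch[x]); }
  }
}

static RTree propose_nni(const RTree& S) {
  RTree T = S;
  std::vector<int> cand;
  for (int v = S.nl; v < S.nn(); ++v)
    if (v != S.root && S.par[v] >= 0) cand.push_back(v);  // internal edge above v
  if (cand.empty()) return T;
  int v = cand[rint((int)cand.size())];
  int u = S.par[v];
  int c = (S.lch[u] == v) ? S.rch[u] : S.lch[u];
  int w = (unif_rand() < 0.5) ? S.lch[v] : S.rch[v];
  T.par[c] = v; T.par[w] = u;
  T.rebuild();
  return T;
}

// re-root the (unrooted version of) S above node v; root id is preserved
static RTree reroot_above(const RTree& S, int v) {
  int n = S.nn();
  RTree T; T.nl = S.nl; T.par.assign(n, -1);
  // unrooted adjacency: edges (x, par[x]) for x != root, except that the two
  // root edges fuse into one
  std::vector<std::vector<int>> adj(n);
  int rl = S.lch[S.root], rr = S.rch[S.root];
  for (int x = 0; x < n; ++x) {
    if (x == S.root || S.par[x] < 0) continue;
    if (S.par[x] == S.root) continue;
    adj[x].push_back(S.par[x]); adj[S.par[x]].push_back(x);
  }
  adj[rl].push_back(rr); adj[rr].push_back(rl);
  // neighbor of v on the path toward the old parent (v != root guaranteed)
  int u = (S.par[v] == S.root) ? (v == rl ? rr : rl) : S.par[v];
  // orient: new root (reuse S.root id) has children v and u
  T.par[v] = S.root; T.par[u] = S.root;
  std::vector<std::pair<int,int>> st{{v, u}, {u, v}};
  while (!st.empty()) {
    auto [x, from] = st.back(); st.pop_back();
    for (int w : adj[x]) if (w != from) { T.par[w] = x; st.push_back({w, x}); }
  }
  T.rebuild();
  return T;
}

static RTree propose_reroot(const RTree& S) {
  std::vector<int> cand;
  for (int v = 0; v < S.nn(); ++v)
    if (v != S.root && v != S.rch[S.root]) cand.push_back(v);
  if (cand.empty()) return S;
  return reroot_above(S, cand[rint((int)cand.size())]);
}

static RTree propose_spr(const RTree& S) {
  if (S.nl < 4) return propose_nni(S);
  std::vector<int> cand;
  for (int v = 0; v < S.nn(); ++v)
    if (v != S.root && S.par[v] >= 0 && S.par[v] != S.root) cand.push_back(v);
  if (cand.empty()) return S;
  int v = cand[rint((int)cand.size())];
  RTree T = S;
  int p = S.par[v], s = (S.lch[p] == v) ? S.rch[p] : S.lch[p], g = S.par[p];
  T.par[s] = g;                       // detach p (and the subtree at v)
  std::vector<char> off(S.nn(), 0);
  subtree_mark(S, v, off); off[p] = 1;
  std::vector<int> tgt;
  for (int w = 0; w < S.nn(); ++w)
    if (!off[w] && w != S.root) tgt.push_back(w);
  if (tgt.empty()) return S;
  int w = tgt[rint((int)tgt.size())];
  int pw = T.par[w];                  // parent after detachment
  T.par[w] = p; T.par[p] = pw; T.par[v] = p;
  T.rebuild();
  return T;
}

static RTree propose_species(const RTree& S, const std::vector<double>& mix) {
  double u = unif_rand() * (mix[0] + mix[1] + mix[2]);
  if (u < mix[0]) return propose_nni(S);
  if (u < mix[0] + mix[1]) return propose_spr(S);
  return propose_reroot(S);
}

// exported for the proposal-validity / irreducibility tests
// [[Rcpp::export]]
IntegerVector cpp_propose_species(IntegerVector s_parent, std::string move) {
  RTree S = rtree_from_parent(s_parent);
  RTree T = (move == "nni") ? propose_nni(S)
          : (move == "spr") ? propose_spr(S)
          : propose_reroot(S);
  return IntegerVector(T.par.begin(), T.par.end());
}

// ---------------------------------------------------------------------------
// Chain
// ---------------------------------------------------------------------------
struct Family {
  int nl = 0, fns = 0;
  std::vector<int> species;                      // global species ids, sorted
  std::vector<int> copies;                       // gene copies per local species
  std::vector<UTree> topos;
  std::vector<std::vector<std::string>> tsplits; // per topology, for mulRF
  std::vector<double> logw, cumw;                // input weights
  std::vector<double> m;                         // scaling constants, length J
};

struct Model {
  int J = 0;
  std::vector<int> didx;   // 0=dup 1=loss 2=ils 3=mulrf
  bool use_mulrf = false;
};

struct Chain {
  int ns = 0, N = 0;
  RTree S;
  uint64_t Shash = 0;
  std::vector<Family> fams;
  Model mod;
  std::vector<std::vector<double>> lambda;  // N x J
  std::vector<double> lambda0;              // J
  double hyper_mean = 1.0;
  std::vector<int> gidx;
  std::vector<std::array<double,4>> curd;
  // caches
  std::unordered_map<uint64_t, std::array<double,4>> dcache;
  struct RestS { RTree R; std::vector<std::string> esplits; };
  std::unordered_map<uint64_t, RestS> rcache;  // per (Shash, fam)
  DistCtx cx;
  bool use_cache = true;

  const RestS& restricted(uint64_t shash, const RTree& S_, int i) {
    uint64_t key = mix64(shash ^ mix64((uint64_t)i + 7));
    if (use_cache) {
      auto it = rcache.find(key);
      if (it != rcache.end()) return it->second;
    } else rcache.erase(key);
    RestS rs;
    rs.R = restrict_rtree(S_, fams[i].species);
    if (mod.use_mulrf) rs.esplits = extended_splits(rs.R, fams[i].copies);
    auto res = rcache.insert_or_assign(key, std::move(rs));
    return res.first->second;
  }

  std::array<double,4> dist(uint64_t shash, const RTree& S_, int i, int t) {
    uint64_t key = mix64(shash ^ mix64((uint64_t)(i * 1000003 + t) + 13));
    if (use_cache) {
      auto it = dcache.find(key);
      if (it != dcache.end()) return it->second;
    }
    const RestS& rs = restricted(shash, S_, i);
    DV dv = distvec(fams[i].topos[t], rs.R, mod.use_mulrf, &fams[i].tsplits[t],
                    cx, mod.use_mulrf ? &rs.esplits : nullptr);
    std::array<double,4> d{dv.d[0], dv.d[1], dv.d[2], dv.d[3]};
    dcache.emplace(key, d);
    return d;
  }

  double logf(int i, const std::array<double,4>& d, const std::vector<double>& lam) const {
    double s = 0;
    for (int j = 0; j < mod.J; ++j)
      s -= d[mod.didx[j]] / (fams[i].m[j] * lam[j]);
    return s;
  }
  double logf(int i, const std::array<double,4>& d) const { return logf(i, d, lambda[i]); }

  double lp_lambda_row(int i) const {
    double s = 0;
    for (int j = 0; j < mod.J; ++j)
      s += -lambda[i][j] / lambda0[j] - std::log(lambda0[j]);
    return s;
  }
  double lp_lambda0() const {
    double s = 0;
    for (int j = 0; j < mod.J; ++j)
      s += -lambda0[j] / hyper_mean - std::log(hyper_mean);
    return s;
  }
  double log_posterior() const {
    double s = lp_lambda0();
    for (int i = 0; i < N; ++i)
      s += fams[i].logw[gidx[i]] + logf(i, curd[i]) + lp_lambda_row(i);
    // uniform species prior: -log (2n-3)!!
    for (int k = 3; k <= 2 * ns - 3; k += 2) s -= std::log((double)k);
    return s;
  }
};

// one NNI Metropolis walk over all topologies of family i, targeting the
// unscaled density against Starget; used by the exchange update
static void aux_walk(Chain& C, int i, const RTree& Srest, const std::vector<double>& lam,
                     int steps, UTree& A, std::array<double,4>& dA) {
  DV dv = distvec(A, Srest, C.mod.use_mulrf, nullptr, C.cx);
  dA = {dv.d[0], dv.d[1], dv.d[2], dv.d[3]};
  if (A.nl < 4) return;
  for (int s = 0; s < steps; ++s) {
    std::vector<int> ie;
    for (int e = 0; e < A.ne(); ++e)
      if (A.e1[e] >= A.nl && A.e2[e] >= A.nl) ie.push_back(e);
    if (ie.empty()) return;
    int e = ie[rint((int)ie.size())];
    UTree B = A;
    int u = B.e1[e], v = B.e2[e];
    std::vector<int> eu, ev;
    for (auto& [ee, w] : B.adj[u]) if (ee != e) eu.push_back(ee);
    for (auto& [ee, w] : B.adj[v]) if (ee != e) ev.push_back(ee);
    int ea = eu[rint(2)], eb = ev[rint(2)];
    // swap: endpoint u of ea becomes v, endpoint v of eb becomes u
    if (B.e1[ea] == u) B.e1[ea] = v; else B.e2[ea] = v;
    if (B.e1[eb] == v) B.e1[eb] = u; else B.e2[eb] = u;
    B.build_adj();
    B.o_order.clear();  // orientation is stale after the swap
    DV dvb = distvec(B, Srest, C.mod.use_mulrf, nullptr, C.cx);
    std::array<double,4> dB{dvb.d[0], dvb.d[1], dvb.d[2], dvb.d[3]};
    double la = 0, lb = 0;
    for (int j = 0; j < C.mod.J; ++j) {
      la -= dA[C.mod.didx[j]] / (C.fams[i].m[j] * lam[j]);
      lb -= dB[C.mod.didx[j]] / (C.fams[i].m[j] * lam[j]);
    }
    if (std::log(unif_rand()) < lb - la) { A = B; dA = dB; }
  }
}

struct Cfg {
  int iterations = 1000, k = 4, thin = 1, aux_len = 100;
  double burn_in = 0.5;
  std::vector<double> mix{0.6, 0.2, 0.2};
  bool exchange = false, anneal = false;
  double kT_start = 1.0, kT_end = 1e-3;
  double pre_anneal = 1.0;   // burn-in starts at this temperature ...
  double pre_floor = 1.0;    // ... cools to this floor, then samples at kT=1
  double sigma_lambda = 0.5, sigma_lambda0 = 0.5;
  bool up_species = true, up_genes = true, up_lambda = true, up_lambda0 = true;
  int gene_only = -1;  // restrict gene-tree updates to one family (tests/plumbing)
};

// Generalized multiple-try Metropolis species-tree update (optionally with the
// exchange correction for the partition function).
static bool update_species(Chain& C, const Cfg& cfg, double invT) {
  int k = cfg.k, N = C.N;
  std::vector<RTree> ys(k);
  std::vector<uint64_t> yh(k);
  std::vector<std::vector<std::array<double,4>>> yd(k, std::vector<std::array<double,4>>(N));
  std::vector<double> lwy(k);
  for (int c = 0; c < k; ++c) {
    ys[c] = propose_species(C.S, cfg.mix);
    yh[c] = rtree_hash(ys[c]);
    double s = 0;
    for (int i = 0; i < N; ++i) {
      yd[c][i] = C.dist(yh[c], ys[c], i, C.gidx[i]);
      s += C.logf(i, yd[c][i]);
    }
    lwy[c] = invT * s;
  }
  int j = sample_logw(lwy);
  double lWy = lwy[j] - logsumexp(lwy);
  // reverse shadows from the selected candidate
  std::vector<double> lwx(k);
  double fx = 0;
  for (int i = 0; i < N; ++i) fx += C.logf(i, C.curd[i]);
  lwx[0] = invT * fx;  // x itself occupies the matching slot
  for (int c = 1; c < k; ++c) {
    RTree xs = propose_species(ys[j], cfg.mix);
    uint64_t xh = rtree_hash(xs);
    double s = 0;
    for (int i = 0; i < N; ++i) s += C.logf(i, C.dist(xh, xs, i, C.gidx[i]));
    lwx[c] = invT * s;
  }
  double lWx = lwx[0] - logsumexp(lwx);
  double la = (lwy[j] - invT * fx) + lWx - lWy;  // symmetric kernels
  if (cfg.exchange) {
    // auxiliary gene trees from the model at the proposed state
    double extra = 0;
    for (int i = 0; i < N; ++i) {
      UTree A = C.fams[i].topos[C.gidx[i]];
      std::array<double,4> dA;
      const RTree Rsy = C.restricted(yh[j], ys[j], i).R;
      aux_walk(C, i, Rsy, C.lambda[i], cfg.aux_len, A, dA);
      const RTree Rsx = C.restricted(C.Shash, C.S, i).R;
      DV dvx = distvec(A, Rsx, C.mod.use_mulrf, nullptr, C.cx);
      std::array<double,4> dAx{dvx.d[0], dvx.d[1], dvx.d[2], dvx.d[3]};
      extra += C.logf(i, dAx) - C.logf(i, dA);
    }
    la += invT * extra;
  }
  if (std::log(unif_rand()) < la) {
    C.S = ys[j]; C.Shash = yh[j];
    for (int i = 0; i < N; ++i) C.curd[i] = yd[j][i];
    return true;
  }
  return false;
}

static bool update_gene(Chain& C, const Cfg& cfg, int i, double invT) {
  Family& F = C.fams[i];
  int T = (int)F.topos.size();
  if (T < 2) return false;
  int k = cfg.k;
  std::vector<int> yt(k);
  std::vector<double> lwy(k);
  auto draw = [&]() {
    double u = unif_rand();
    int lo = 0, hi = T - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (F.cumw[mid] < u) lo = mid + 1; else hi = mid; }
    return lo;
  };
  for (int c = 0; c < k; ++c) {
    yt[c] = draw();
    std::array<double,4> d = C.dist(C.Shash, C.S, i, yt[c]);
    lwy[c] = invT * (F.logw[yt[c]] + C.logf(i, d));
  }
  int j = sample_logw(lwy);
  double lWy = lwy[j] - logsumexp(lwy);
  std::vector<double> lwx(k);
  lwx[0] = invT * (F.logw[C.gidx[i]] + C.logf(i, C.curd[i]));
  for (int c = 1; c < k; ++c) {
    int t = draw();
    lwx[c] = invT * (F.logw[t] + C.logf(i, C.dist(C.Shash, C.S, i, t)));
  }
  double lWx = lwx[0] - logsumexp(lwx);
  // independence proposal p(.) = input weights: kernel ratio = g(x)/g(y)
  double la = (lwy[j] - lwx[0]) + (F.logw[C.gidx[i]] - F.logw[yt[j]]) + lWx - lWy;
  if (std::log(unif_rand()) < la) {
    C.gidx[i] = yt[j];
    C.curd[i] = C.dist(C.Shash, C.S, i, yt[j]);
    return true;
  }
  return false;
}

static bool update_lambda_row(Chain& C, const Cfg& cfg, int i, double invT) {
  int k = cfg.k, J = C.mod.J;
  std::vector<std::vector<double>> ys(k, std::vector<double>(J));
  std::vector<double> lwy(k);
  auto target = [&](const std::vector<double>& lam) {
    double s = C.logf(i, C.curd[i], lam);
    for (int j = 0; j < J; ++j) s += -lam[j] / C.lambda0[j] - std::log(C.lambda0[j]);
    return s;
  };
  for (int c = 0; c < k; ++c) {
    for (int j = 0; j < J; ++j)
      ys[c][j] = C.lambda[i][j] * std::exp(cfg.sigma_lambda * norm_rand());
    lwy[c] = invT * target(ys[c]);
  }
  int j = sample_logw(lwy);
  double lWy = lwy[j] - logsumexp(lwy);
  std::vector<double> lwx(k);
  lwx[0] = invT * target(C.lambda[i]);
  for (int c = 1; c < k; ++c) {
    std::vector<double> xs(J);
    for (int jj = 0; jj < J; ++jj)
      xs[jj] = ys[j][jj] * std::exp(cfg.sigma_lambda * norm_rand());
    lwx[c] = invT * target(xs);
  }
  double lWx = lwx[0] - logsumexp(lwx);
  double lq = 0;  // log q(x|y) - log q(y|x) for multiplicative log-normal
  for (int jj = 0; jj < J; ++jj) lq += std::log(ys[j][jj]) - std::log(C.lambda[i][jj]);
  double la = (lwy[j] - lwx[0]) + lq + lWx - lWy;
  if (cfg.exchange) {
    UTree A = C.fams[i].topos[C.gidx[i]];
    std::array<double,4> dA;
    const RTree Rs = C.restricted(C.Shash, C.S, i).R;
    aux_walk(C, i, Rs, ys[j], cfg.aux_len, A, dA);
    la += invT * (C.logf(i, dA, C.lambda[i]) - C.logf(i, dA, ys[j]));
  }
  if (std::log(unif_rand()) < la) { C.lambda[i] = ys[j]; return true; }
  return false;
}

static bool update_lambda0(Chain& C, const Cfg& cfg, double invT) {
  int k = cfg.k, J = C.mod.J;
  auto target = [&](const std::vector<double>& l0) {
    double s = 0;
    for (int j = 0; j < J; ++j) {
      s += -l0[j] / C.hyper_mean - std::log(C.hyper_mean);
      for (int i = 0; i < C.N; ++i)
        s += -C.lambda[i][j] / l0[j] - std::log(l0[j]);
    }
    return s;
  };
  std::vector<std::vector<double>> ys(k, std::vector<double>(J));
  std::vector<double> lwy(k);
  for (int c = 0; c < k; ++c) {
    for (int j = 0; j < J; ++j)
      ys[c][j] = C.lambda0[j] * std::exp(cfg.sigma_lambda0 * norm_rand());
    lwy[c] = invT * target(ys[c]);
  }
  int j = sample_logw(lwy);
  double lWy = lwy[j] - logsumexp(lwy);
  std::vector<double> lwx(k);
  lwx[0] = invT * target(C.lambda0);
  for (int c = 1; c < k; ++c) {
    std::vector<double> xs(J);
    for (int jj = 0; jj < J; ++jj)
      xs[jj] = ys[j][jj] * std::exp(cfg.sigma_lambda0 * norm_rand());
    lwx[c] = invT * target(xs);
  }
  double lWx = lwx[0] - logsumexp(lwx);
  double lq = 0;
  for (int jj = 0; jj < J; ++jj) lq += std::log(ys[j][jj]) - std::log(C.lambda0[jj]);
  double la = (lwy[j] - lwx[0]) + lq + lWx - lWy;
  if (std::log(unif_rand()) < la) { C.lambda0 = ys[j]; return true; }
  return false;
}

// [[Rcpp::export]]
List cpp_run_chain(IntegerVector s_parent, int n_species, List families,
                   NumericMatrix lambda_init, NumericVector lambda0_init,
                   IntegerVector gidx_init, IntegerVector dist_idx,
                   double hyper_mean, List cfg_in) {
  Chain C;
  C.ns = n_species;
  C.S = rtree_from_parent(s_parent);
  C.Shash = rtree_hash(C.S);
  C.hyper_mean = hyper_mean;
  C.mod.J = dist_idx.size();
  C.mod.didx.assign(dist_idx.begin(), dist_idx.end());
  for (int j : C.mod.didx) if (j == 3) C.mod.use_mulrf = true;
  C.N = families.size();
  for (int i = 0; i < C.N; ++i) {
    List fl = families[i];
    Family F;
    F.nl = as<int>(fl["nl"]);
    IntegerVector sp = fl["species"];
    F.species.assign(sp.begin(), sp.end());
    F.fns = (int)F.species.size();
    IntegerVector spp = fl["spp"];
    F.copies.assign(F.fns, 0);
    for (int l = 0; l < spp.size(); ++l) F.copies[spp[l]]++;
    List edges = fl["edges"];
    NumericVector w = fl["weights"];
    NumericVector m = fl["m"];
    F.m.assign(m.begin(), m.end());
    double c = 0;
    for (int t = 0; t < edges.size(); ++t) {
      UTree G = utree_from_edges(edges[t], spp);
      F.tsplits.push_back(utree_splits(G, F.fns));
      F.topos.push_back(std::move(G));
      F.logw.push_back(std::log((double)w[t]));
      c += w[t];
      F.cumw.push_back(c);
    }
    for (auto& x : F.cumw) x /= c;
    C.fams.push_back(std::move(F));
  }
  C.lambda.assign(C.N, std::vector<double>(C.mod.J));
  for (int i = 0; i < C.N; ++i)
    for (int j = 0; j < C.mod.J; ++j) C.lambda[i][j] = lambda_init(i, j);
  C.lambda0.assign(lambda0_init.begin(), lambda0_init.end());
  C.gidx.assign(gidx_init.begin(), gidx_init.end());
  C.curd.resize(C.N);
  for (int i = 0; i < C.N; ++i) C.curd[i] = C.dist(C.Shash, C.S, i, C.gidx[i]);

  Cfg cfg;
  cfg.iterations = as<int>(cfg_in["iterations"]);
  cfg.k = as<int>(cfg_in["k_tries"]);
  cfg.thin = as<int>(cfg_in["thin"]);
  cfg.burn_in = as<double>(cfg_in["burn_in"]);
  NumericVector mix = cfg_in["mix"];
  cfg.mix.assign(mix.begin(), mix.end());
  cfg.exchange = as<bool>(cfg_in["exchange"]);
  cfg.aux_len = as<int>(cfg_in["aux_len"]);
  cfg.anneal = as<bool>(cfg_in["anneal"]);
  cfg.kT_start = as<double>(cfg_in["kT_start"]);
  cfg.kT_end = as<double>(cfg_in["kT_end"]);
  cfg.sigma_lambda = as<double>(cfg_in["sigma_lambda"]);
  cfg.sigma_lambda0 = as<double>(cfg_in["sigma_lambda0"]);
  cfg.up_species = as<bool>(cfg_in["update_species"]);
  cfg.up_genes = as<bool>(cfg_in["update_genes"]);
  cfg.up_lambda = as<bool>(cfg_in["update_lambda"]);
  cfg.up_lambda0 = as<bool>(cfg_in["update_lambda0"]);
  if (cfg_in.containsElementNamed("use_cache"))
    C.use_cache = as<bool>(cfg_in["use_cache"]);
  if (cfg_in.containsElementNamed("gene_family_only"))
    cfg.gene_only = as<int>(cfg_in["gene_family_only"]);
  if (cfg_in.containsElementNamed("pre_anneal"))
    cfg.pre_anneal = as<double>(cfg_in["pre_anneal"]);
  if (cfg_in.containsElementNamed("pre_floor"))
    cfg.pre_floor = as<double>(cfg_in["pre_floor"]);

  int burn = (int)std::floor(cfg.burn_in * cfg.iterations);
  int nsamp = 0;
  for (int it = burn + 1; it <= cfg.iterations; ++it)
    if ((it - burn) % cfg.thin == 0) nsamp++;
  int npar = 2 * C.ns - 1;
  IntegerMatrix out_S(nsamp, npar), out_G(nsamp, C.N);
  NumericMatrix out_l(nsamp, C.N * C.mod.J), out_l0(nsamp, C.mod.J);
  NumericVector out_lp(nsamp);
  IntegerVector out_it(nsamp);
  double acc_S = 0, try_S = 0, acc_G = 0, try_G = 0, acc_l = 0, try_l = 0,
         acc_l0 = 0, try_l0 = 0;

  // best state visited (annealing / ML point estimate)
  double best_lp = R_NegInf;
  std::vector<int> best_par(C.S.par), best_g(C.gidx);
  std::vector<std::vector<double>> best_lambda(C.lambda);
  std::vector<double> best_lambda0(C.lambda0);

  double lr = (cfg.iterations > 1)
    ? std::log(cfg.kT_end / cfg.kT_start) / (cfg.iterations - 1) : 0.0;
  int row = 0;
  for (int it = 1; it <= cfg.iterations; ++it) {
    double invT = 1.0;
    if (cfg.anneal) invT = 1.0 / (cfg.kT_start * std::exp(lr * (it - 1)));
    else if (cfg.pre_anneal > cfg.pre_floor && it <= burn && burn > 1)
      invT = 1.0 / (cfg.pre_anneal *
                    std::exp(std::log(cfg.pre_floor / cfg.pre_anneal) *
                             (it - 1) / (burn - 1)));
    if (cfg.up_species && C.ns >= 3) { try_S++; if (update_species(C, cfg, invT)) acc_S++; }
    if (cfg.up_genes)
      for (int i = 0; i < C.N; ++i) {
        if (cfg.gene_only >= 0 && i != cfg.gene_only) continue;
        try_G++; if (update_gene(C, cfg, i, invT)) acc_G++;
      }
    if (cfg.up_lambda)
      for (int i = 0; i < C.N; ++i) { try_l++; if (update_lambda_row(C, cfg, i, invT)) acc_l++; }
    if (cfg.up_lambda0) { try_l0++; if (update_lambda0(C, cfg, invT)) acc_l0++; }
    double lp = C.log_posterior();
    if (lp > best_lp) {
      best_lp = lp; best_par = C.S.par; best_g = C.gidx;
      best_lambda = C.lambda; best_lambda0 = C.lambda0;
    }
    if (it > burn && (it - burn) % cfg.thin == 0) {
      for (int v = 0; v < npar; ++v) out_S(row, v) = C.S.par[v];
      for (int i = 0; i < C.N; ++i) out_G(row, i) = C.gidx[i];
      for (int i = 0; i < C.N; ++i)
        for (int j = 0; j < C.mod.J; ++j) out_l(row, i * C.mod.J + j) = C.lambda[i][j];
      for (int j = 0; j < C.mod.J; ++j) out_l0(row, j) = C.lambda0[j];
      out_lp[row] = lp; out_it[row] = it;
      row++;
    }
    // keep caches bounded on long runs
    if (C.dcache.size() > 4000000) { C.dcache.clear(); C.rcache.clear(); }
  }

  NumericMatrix best_l(C.N, C.mod.J);
  for (int i = 0; i < C.N; ++i)
    for (int j = 0; j < C.mod.J; ++j) best_l(i, j) = best_lambda[i][j];
  return List::create(
    _["species_parent"] = out_S, _["gene_index"] = out_G,
    _["lambda"] = out_l, _["lambda0"] = out_l0,
    _["log_posterior"] = out_lp, _["iteration"] = out_it,
    _["acc"] = NumericVector::create(
      _["species"] = try_S ? acc_S / try_S : NA_REAL,
      _["genes"] = try_G ? acc_G / try_G : NA_REAL,
      _["lambda"] = try_l ? acc_l / try_l : NA_REAL,
      _["lambda0"] = try_l0 ? acc_l0 / try_l0 : NA_REAL),
    _["best"] = List::create(
      _["species_parent"] = IntegerVector(best_par.begin(), best_par.end()),
      _["gene_index"] = IntegerVector(best_g.begin(), best_g.end()),
      _["lambda"] = best_l,
      _["lambda0"] = NumericVector(best_lambda0.begin(), best_lambda0.end()),
      _["log_posterior"] = best_lp),
    _["final"] = List::create(
      _["species_parent"] = IntegerVector(C.S.par.begin(), C.S.par.end()),
      _["gene_index"] = IntegerVector(C.gidx.begin(), C.gidx.end()),
      _["log_posterior"] = C.log_posterior()));
}

// ---------------------------------------------------------------------------
// Nonparametric gene-tree uncertainty: length-dependent NNI perturbation
// ---------------------------------------------------------------------------

// canonical 64-bit key of a (distinct-leaf-labeled) unrooted topology:
// Merkle hash of the tree rooted at leaf 0's neighbor with order-invariant
// child combination; linear time, collision probability ~ 2^-64
static uint64_t utree_key_node(const UTree& G, int v, int from) {
  if (v < G.nl) return mix64((uint64_t)v + 1);
  uint64_t acc = 0x243f6a8885a308d3ULL;
  std::vector<uint64_t> hs;
  for (auto& [e, w] : G.adj[v]) if (w != from) hs.push_back(utree_key_node(G, w, v));
  std::sort(hs.begin(), hs.end());
  for (uint64_t h : hs) acc = mix64(acc * 5 + h);
  return acc;
}
static uint64_t utree_key(const UTree& G) {
  if (G.nl < 3) return 1;
  int anchor = G.adj[0][0].second;
  return utree_key_node(G, anchor, -1);
}

// [[Rcpp::export]]
List cpp_perturb_draws(IntegerMatrix edges, NumericVector edge_len, int n_leaves,
                       double pT, double pB, int n_draws) {
  IntegerVector spp(n_leaves);
  for (int i = 0; i < n_leaves; ++i) spp[i] = i;
  UTree G0 = utree_from_edges(edges, spp);
  std::vector<int> internal;
  double lmin = R_PosInf;
  for (int e = 0; e < G0.ne(); ++e)
    if (G0.e1[e] >= n_leaves && G0.e2[e] >= n_leaves) {
      internal.push_back(e);
      if (edge_len[e] < lmin) lmin = edge_len[e];
    }
  std::vector<double> pe(G0.ne(), 0.0);
  for (int e : internal)
    pe[e] = std::min(1.0, pB * (edge_len[e] > 0 ? lmin / edge_len[e] : 1.0));
  double pTeff = std::min(1.0, pT);
  uint64_t key0 = utree_key(G0);
  std::unordered_map<uint64_t, int> counts;
  std::unordered_map<uint64_t, IntegerMatrix> reps;
  counts[key0] = 0;
  reps[key0] = edges;
  for (int d = 0; d < n_draws; ++d) {
    if (unif_rand() >= pTeff || internal.empty()) { counts[key0]++; continue; }
    UTree G = G0;
    bool changed = false;
    for (int e : internal) {
      if (unif_rand() >= pe[e]) continue;
      int u = G.e1[e], v = G.e2[e];
      std::vector<int> eu, ev;
      for (auto& [ee, w] : G.adj[u]) if (ee != e) eu.push_back(ee);
      for (auto& [ee, w] : G.adj[v]) if (ee != e) ev.push_back(ee);
      int ea = eu[rint(2)], eb = ev[rint(2)];
      if (G.e1[ea] == u) G.e1[ea] = v; else G.e2[ea] = v;
      if (G.e1[eb] == v) G.e1[eb] = u; else G.e2[eb] = u;
      G.build_adj();
      G.o_order.clear();
      changed = true;
    }
    uint64_t key = changed ? utree_key(G) : key0;
    auto it = counts.find(key);
    if (it == counts.end()) {
      counts[key] = 1;
      IntegerMatrix em(G.ne(), 2);
      for (int e = 0; e < G.ne(); ++e) { em(e, 0) = G.e1[e]; em(e, 1) = G.e2[e]; }
      reps[key] = em;
    } else it->second++;
  }
  std::vector<uint64_t> keys;
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int K = (int)keys.size();
  List out_edges(K);
  IntegerVector out_counts(K);
  LogicalVector is_true(K);
  for (int i = 0; i < K; ++i) {
    out_edges[i] = reps[keys[i]];
    out_counts[i] = counts[keys[i]];
    is_true[i] = (keys[i] == key0);
  }
  return List::create(_["edges"] = out_edges, _["counts"] = out_counts,
                      _["is_true"] = is_true);
}
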