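#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Unrooted binary topology over n taxa. Vertices are 1-based: leaves 1..n,
// internal vertices n+1..2n-2; 2n-3 edges held as two parallel endpoint
// arrays. All randomness comes from R's RNG (unif_rand) so that set.seed()
// gives bit-identical runs.

struct Tree {
  int n;
  std::vector<int> a, b; // edge endpoints
  int nv() const { return 2 * n - 2; }
  int ne() const { return (int)a.size(); }
};

static Tree tree_from_edge(const IntegerMatrix& edge, int n_taxa) {
  Tree t;
  t.n = n_taxa;
  int m = edge.nrow();
  t.a.resize(m);
  t.b.resize(m);
  for (int i = 0; i < m; ++i) {
    t.a[i] = edge(i, 0);
    t.b[i] = edge(i, 1);
  }
  return t;
}

static IntegerMatrix edge_from_tree(const Tree& t) {
  IntegerMatrix e(t.ne(), 2);
  for (int i = 0; i < t.ne(); ++i) {
    e(i, 0) = t.a[i];
    e(i, 1) = t.b[i];
  }
  return e;
}

// incidence lists: for each vertex the incident edge indices, in edge order
static void build_incidence(const Tree& t, std::vector<int>& deg,
                            std::vector<int>& inc) {
  int V = t.nv();
  deg.assign(V + 1, 0);
  inc.assign(3 * (V + 1), -1);
  for (int i = 0; i < t.ne(); ++i) {
    int u = t.a[i], v = t.b[i];
    inc[3 * u + deg[u]++] = i;
    inc[3 * v + deg[v]++] = i;
  }
}

static inline int other_end(const Tree& t, int ei, int v) {
  return t.a[ei] == v ? t.b[ei] : t.a[ei];
}

// ---------------------------------------------------------------------------
// Fitch length. pat is a P x n integer matrix of 4-bit base masks (A=1, C=2,
// G=4, T=8; ambiguity = union of bits), one column per taxon; w holds the
// pattern multiplicities. The tree is rooted on the edge incident to leaf 1
// and the standard intersection/union post-order pass is applied.
// ---------------------------------------------------------------------------
static double fitch_len(const Tree& t, const int* pat, int P, const double* w,
                        std::vector<int>& buf, std::vector<int>& order,
                        std::vector<int>& parent, std::vector<int>& deg,
                        std::vector<int>& inc) {
  int n = t.n;
  build_incidence(t, deg, inc);
  // root r = the internal vertex adjacent to leaf 1
  int e1 = inc[3 * 1 + 0];
  int r = other_end(t, e1, 1);
  int V = t.nv();
  parent.assign(V + 1, 0);
  order.clear();
  order.push_back(r);
  parent[r] = 1;
  for (size_t k = 0; k < order.size(); ++k) {
    int v = order[k];
    for (int j = 0; j < 3; ++j) {
      int ei = inc[3 * v + j];
      int u = other_end(t, ei, v);
      if (u != parent[v] && u > n) {
        parent[u] = v;
        order.push_back(u);
      }
    }
  }
  buf.assign((size_t)(n - 2) * P, 0);
  double cost = 0.0;
  // post-order: reverse of the preorder above
  for (int k = (int)order.size() - 1; k >= 0; --k) {
    int v = order[k];
    const int* s1 = NULL;
    const int* s2 = NULL;
    for (int j = 0; j < 3; ++j) {
      int ei = inc[3 * v + j];
      int u = other_end(t, ei, v);
      if (u == parent[v]) continue;
      const int* su =
          (u <= n) ? pat + (size_t)(u - 1) * P : &buf[(size_t)(u - n - 1) * P];
      if (s1 == NULL) s1 = su; else s2 = su;
    }
    int* sv = &buf[(size_t)(v - n - 1) * P];
    for (int s = 0; s < P; ++s) {
      int x = s1[s] & s2[s];
      if (x == 0) {
        x = s1[s] | s2[s];
        cost += w[s];
      }
      sv[s] = x;
    }
  }
  const int* l1 = pat; // leaf 1 = first column
  const int* sr = &buf[(size_t)(r - n - 1) * P];
  for (int s = 0; s < P; ++s)
    if ((sr[s] & l1[s]) == 0) cost += w[s];
  return cost;
}

struct FitchWork {
  std::vector<int> buf, order, parent, deg, inc;
};

static double fitch_len(const Tree& t, const int* pat, int P, const double* w,
                        FitchWork& wk) {
  return fitch_len(t, pat, P, w, wk.buf, wk.order, wk.parent, wk.deg, wk.inc);
}

// [[Rcpp::export]]
double cpp_fitch_length(IntegerMatrix edge, int n_taxa, IntegerMatrix pat,
                        NumericVector w) {
  Tree t = tree_from_edge(edge, n_taxa);
  FitchWork wk;
  return fitch_len(t, pat.begin(), pat.nrow(), w.begin(), wk);
}

// ---------------------------------------------------------------------------
// Moves
// ---------------------------------------------------------------------------

static inline int runif_int(int k) { // uniform on 0..k-1
  int x = (int)std::floor(unif_rand() * k);
  return x >= k ? k - 1 : x;
}

// Deterministic NNI on the internal edge with matrix index e; arrangement
// arr in {0, 1} selects which neighbour of v is exchanged with the second
// neighbour of u (u, v = stored endpoints of the chosen internal edge). The
// central edge keeps its index and endpoints, so applying the same
// (edge, arrangement) twice restores the original topology.
static void apply_nni(Tree& t, int e, int arr, std::vector<int>& deg,
                      std::vector<int>& inc, int* edited = NULL) {
  build_incidence(t, deg, inc);
  int n = t.n;
  if (e < 0 || e >= t.ne() || t.a[e] <= n || t.b[e] <= n)
    stop("not an internal edge");
  int u = t.a[e], v = t.b[e];
  int iu[2], iv[2], ku = 0, kv = 0;
  for (int j = 0; j < 3; ++j) {
    if (inc[3 * u + j] != e) iu[ku++] = inc[3 * u + j];
    if (inc[3 * v + j] != e) iv[kv++] = inc[3 * v + j];
  }
  int eb = iu[1];          // subtree B hanging off u
  int ez = iv[arr];        // subtree Z hanging off v
  int B = other_end(t, eb, u);
  int Z = other_end(t, ez, v);
  // reconnect: B moves to v, Z moves to u
  if (t.a[eb] == B) t.a[eb] = Z; else t.b[eb] = Z;
  if (t.a[ez] == Z) t.a[ez] = B; else t.b[ez] = B;
  if (edited) { edited[0] = e; edited[1] = eb; edited[2] = ez; }
}

static void random_nni(Tree& t, std::vector<int>& deg, std::vector<int>& inc,
                       int* edited = NULL) {
  int rank = runif_int(t.n - 3);
  int arr = runif_int(2);
  int n = t.n, e = -1, seen = 0;
  for (int i = 0; i < t.ne(); ++i) {
    if (t.a[i] > n && t.b[i] > n) {
      if (seen == rank) { e = i; break; }
      ++seen;
    }
  }
  apply_nni(t, e, arr, deg, inc, edited);
}

// SPR: cut a uniformly chosen edge on a uniformly chosen side, suppress the
// degree-2 vertex left behind, regraft the pruned subtree onto a uniformly
// chosen eligible edge of the remainder. Regrafting onto the merged edge
// (which recreates the source topology) is ineligible; configurations with no
// eligible destination redraw the cut edge.
static void random_spr(Tree& t, std::vector<int>& deg, std::vector<int>& inc,
                       std::vector<char>& inprune, std::vector<int>& stack,
                       std::vector<int>& eligible, int* edited = NULL) {
  build_incidence(t, deg, inc);
  for (int attempt = 0; attempt < 10000; ++attempt) {
    int e = runif_int(t.ne());
    int s = (unif_rand() < 0.5) ? t.a[e] : t.b[e];
    int v = other_end(t, e, s);
    if (deg[v] == 1) continue; // remainder would be a lone leaf
    // mark the pruned component (containing s, not crossing e)
    inprune.assign(t.nv() + 1, 0);
    stack.clear();
    stack.push_back(s);
    inprune[s] = 1;
    while (!stack.empty()) {
      int x = stack.back();
      stack.pop_back();
      for (int j = 0; j < deg[x]; ++j) {
        int ei = inc[3 * x + j];
        if (ei == e) continue;
        int u = other_end(t, ei, x);
        if (!inprune[u]) { inprune[u] = 1; stack.push_back(u); }
      }
    }
    int j1 = -1, j2 = -1;
    for (int j = 0; j < 3; ++j) {
      int ei = inc[3 * v + j];
      if (ei == e) continue;
      if (j1 < 0) j1 = ei; else j2 = ei;
    }
    eligible.clear();
    for (int g = 0; g < t.ne(); ++g) {
      if (g == e || g == j1 || g == j2) continue;
      if (inprune[t.a[g]] || inprune[t.b[g]]) continue;
      eligible.push_back(g);
    }
    if (eligible.empty()) continue;
    int g = eligible[runif_int((int)eligible.size())];
    int x = other_end(t, j1, v), y = other_end(t, j2, v);
    int p = t.a[g], q = t.b[g];
    // j1 becomes the merged edge (x, y)
    if (t.a[j1] == v) t.a[j1] = y; else t.b[j1] = y;
    // g is subdivided by v: g = (p, v), j2 = (v, q)
    if (t.a[g] == q) t.a[g] = v; else t.b[g] = v;
    t.a[j2] = v;
    t.b[j2] = q;
    if (edited) { edited[0] = e; edited[1] = j1; edited[2] = g; }
    return;
  }
  stop("SPR failed to find an eligible regraft (malformed tree?)");
}

// [[Rcpp::export]]
List cpp_nni(IntegerMatrix edge, int n_taxa) {
  Tree t = tree_from_edge(edge, n_taxa);
  std::vector<int> deg, inc;
  int edited[3];
  random_nni(t, deg, inc, edited);
  return List::create(_["edge"] = edge_from_tree(t),
                      _["edited"] = IntegerVector::create(
                          edited[0] + 1, edited[1] + 1, edited[2] + 1));
}

// [[Rcpp::export]]
IntegerMatrix cpp_nni_apply(IntegerMatrix edge, int n_taxa, int edge_index,
                            int arr) {
  Tree t = tree_from_edge(edge, n_taxa);
  std::vector<int> deg, inc;
  apply_nni(t, edge_index - 1, arr - 1, deg, inc);
  return edge_from_tree(t);
}

// [[Rcpp::export]]
List cpp_spr(IntegerMatrix edge, int n_taxa) {
  Tree t = tree_from_edge(edge, n_taxa);
  std::vector<int> deg, inc, stack, eligible;
  std::vector<char> inprune;
  int edited[3];
  random_spr(t, deg, inc, inprune, stack, eligible, edited);
  return List::create(_["edge"] = edge_from_tree(t),
                      _["edited"] = IntegerVector::create(
                          edited[0] + 1, edited[1] + 1, edited[2] + 1));
}

// ---------------------------------------------------------------------------
// Annealing engine. Metropolis acceptance on the homoplasy index
// HI = 1 - K_eff / L (HI = 0 when L = 0), alternating NNI/SPR proposals,
// n moves per temperature, HI recorded every l moves, optional topology
// snapshots every l_tree moves at designated blocks. Schedules: 0 = linear
// (T_k = T0 - (k-1) m, stop below T_floor), 1 = geometric (T *= alpha),
// 2 = constant (requires a move budget). Freezing: freeze_window consecutive
// temperature blocks without a new best HI.
// ---------------------------------------------------------------------------

static inline double hi_of(double L, double K_eff) {
  return (L <= 0.0) ? 0.0 : 1.0 - K_eff / L;
}

// [[Rcpp::export]]
List cpp_anneal(IntegerMatrix edge0, int n_taxa, IntegerMatrix pat,
                NumericVector w, double K_eff, int sched_kind, double T0,
                double m, double alpha, double T_floor, int n_moves, int l,
                int l_tree, int freeze_window, double budget,
                IntegerVector tree_blocks, bool nni_only,
                bool record_decisions) {
  Tree t = tree_from_edge(edge0, n_taxa);
  FitchWork wk;
  std::vector<int> deg, inc, stack, eligible;
  std::vector<char> inprune;
  const int P = pat.nrow();
  const int* pp = pat.begin();
  const double* pw = w.begin();

  double L = fitch_len(t, pp, P, pw, wk);
  double HI = hi_of(L, K_eff);
  Tree best = t;
  double bestL = L, bestHI = HI;

  std::vector<double> blockT, hi_samples;
  std::vector<int> block_prop, block_acc, block_nni, block_spr, block_nsamp;
  std::vector<int> snap_block, snap_move;
  std::vector<std::vector<int>> snaps;
  std::vector<unsigned char> decisions;
  std::unordered_set<int> sample_blocks(tree_blocks.begin(),
                                        tree_blocks.end());

  long long total_prop = 0;
  int freeze = 0;
  std::string term = "floor";
  double Tg = T0;
  bool stop_all = false;

  for (int block = 1;; ++block) {
    double T;
    if (sched_kind == 0) {
      T = T0 - (double)(block - 1) * m;
      if (T < T_floor) { term = "floor"; break; }
    } else if (sched_kind == 1) {
      T = Tg;
      if (T < T_floor) { term = "floor"; break; }
    } else {
      T = T0;
    }
    bool improved = false;
    bool take_snaps = sample_blocks.count(block) > 0;
    int acc = 0, nniC = 0, sprC = 0, nsamp = 0, done = 0;
    Tree cand;
    for (int i = 1; i <= n_moves; ++i) {
      if (budget > 0 && (double)total_prop >= budget) {
        term = "budget";
        stop_all = true;
        break;
      }
      bool isNNI = nni_only || (total_prop % 2 == 0);
      cand = t;
      if (isNNI) {
        random_nni(cand, deg, inc);
        ++nniC;
      } else {
        random_spr(cand, deg, inc, inprune, stack, eligible);
        ++sprC;
      }
      ++total_prop;
      ++done;
      double Lc = fitch_len(cand, pp, P, pw, wk);
      double HIc = hi_of(Lc, K_eff);
      double delta = HIc - HI;
      bool accept;
      if (delta <= 0.0) {
        accept = true;
      } else {
        double u = unif_rand();
        accept = (u < std::exp(-delta / T));
      }
      if (record_decisions) decisions.push_back(accept ? 1 : 0);
      if (accept) {
        std::swap(t.a, cand.a);
        std::swap(t.b, cand.b);
        L = Lc;
        HI = HIc;
        ++acc;
        if (HI < bestHI) {
          bestHI = HI;
          bestL = L;
          best = t;
          improved = true;
        }
      }
      if (i % l == 0) {
        hi_samples.push_back(HI);
        ++nsamp;
      }
      if (take_snaps && i % l_tree == 0) {
        snap_block.push_back(block);
        snap_move.push_back(i);
        std::vector<int> s(2 * t.ne());
        for (int k = 0; k < t.ne(); ++k) {
          s[k] = t.a[k];
          s[t.ne() + k] = t.b[k];
        }
        snaps.push_back(std::move(s));
      }
      if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    if (done > 0) {
      blockT.push_back(T);
      block_prop.push_back(done);
      block_acc.push_back(acc);
      block_nni.push_back(nniC);
      block_spr.push_back(sprC);
      block_nsamp.push_back(nsamp);
    }
    if (stop_all) break;
    if (improved) {
      freeze = 0;
    } else if (++freeze >= freeze_window) {
      term = "frozen";
      break;
    }
    if (sched_kind == 1) Tg *= alpha;
    if (sched_kind == 2 && budget <= 0) stop("constant schedule requires a move budget");
  }

  int ns = (int)snaps.size();
  List tree_list(ns);
  for (int k = 0; k < ns; ++k) {
    int ne = (int)snaps[k].size() / 2;
    IntegerMatrix e(ne, 2);
    for (int j = 0; j < ne; ++j) {
      e(j, 0) = snaps[k][j];
      e(j, 1) = snaps[k][ne + j];
    }
    tree_list[k] = e;
  }
  return List::create(
      _["block_T"] = wrap(blockT), _["block_proposed"] = wrap(block_prop),
      _["block_accepted"] = wrap(block_acc), _["block_nni"] = wrap(block_nni),
      _["block_spr"] = wrap(block_spr), _["block_nsamples"] = wrap(block_nsamp),
      _["hi"] = wrap(hi_samples), _["snap_block"] = wrap(snap_block),
      _["snap_move"] = wrap(snap_move), _["snap_trees"] = tree_list,
      _["final_edge"] = edge_from_tree(t), _["final_L"] = L,
      _["final_HI"] = HI, _["best_edge"] = edge_from_tree(best),
      _["best_L"] = bestL, _["best_HI"] = bestHI,
      _["total_proposed"] = (double)total_prop, _["termination"] = term,
      _["decisions"] = wrap(decisions));
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration by recursive edge addition (test/certification
// oracle at small n). Returns the optimal length, the number of topologies
// visited, and every optimal edge matrix.
// ---------------------------------------------------------------------------

struct ExhState {
  int n;
  const int* pat;
  int P;
  const double* w;
  FitchWork wk;
  double bestL;
  long long count;
  std::vector<std::vector<int>> best;
};

static void exh_recurse(Tree& t, int next_leaf, ExhState& st) {
  if (next_leaf > st.n) {
    ++st.count;
    double L = fitch_len(t, st.pat, st.P, st.w, st.wk);
    if (L < st.bestL - 1e-9) {
      st.bestL = L;
      st.best.clear();
    }
    if (L < st.bestL + 1e-9) {
      std::vector<int> s(2 * t.ne());
      for (int k = 0; k < t.ne(); ++k) {
        s[k] = t.a[k];
        s[t.ne() + k] = t.b[k];
      }
      st.best.push_back(std::move(s));
    }
    return;
  }
  int w = st.n + next_leaf - 2; // new internal vertex
  int ne = t.ne();
  for (int e = 0; e < ne; ++e) {
    int oa = t.a[e], ob = t.b[e];
    t.b[e] = w;
    t.a.push_back(w);
    t.b.push_back(ob);
    t.a.push_back(w);
    t.b.push_back(next_leaf);
    exh_recurse(t, next_leaf + 1, st);
    t.a.resize(ne);
    t.b.resize(ne);
    t.a[e] = oa;
    t.b[e] = ob;
  }
}

// [[Rcpp::export]]
List cpp_exhaustive(int n_taxa, IntegerMatrix pat, NumericVector w) {
  if (n_taxa < 4) stop("need at least 4 taxa");
  ExhState st;
  st.n = n_taxa;
  st.pat = pat.begin();
  st.P = pat.nrow();
  st.w = w.begin();
  st.bestL = R_PosInf;
  st.count = 0;
  Tree t;
  t.n = n_taxa;
  int c = n_taxa + 1;
  t.a = {1, 2, 3};
  t.b = {c, c, c};
  exh_recurse(t, 4, st);
  int nb = (int)st.best.size();
  List best(nb);
  for (int k = 0; k < nb; ++k) {
    int ne = (int)st.best[k].size() / 2;
    IntegerMatrix e(ne, 2);
    for (int j = 0; j < ne; ++j) {
      e(j, 0) = st.best[k][j];
      e(j, 1) = st.best[k][ne + j];
    }
    best[k] = e;
  }
  return List::create(_["best_length"] = st.bestL,
                      _["n_topologies"] = (double)st.count,
                      _["best_edges"] = best);
}
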