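// Core engine for signed gene-order rearrangement search.
//
// Genomes are signed permutations of 1..n (values +-g), circular or linear.
// The three elementary rearrangements are inversion, transposition and
// reverse transposition.  Equivalent operations (the circular ambiguities of
// which block moved) are generated once: a circular transposition is fully
// determined by its unordered triple of cut junctions, a reverse
// transposition contributes three distinct children per triple, and an
// inversion is deduplicated against the inversion of its complement block.
//
// Two admissible pruning tests accelerate the depth-first search:
//   HT1 (shared blocks): a rearrangement may only cut at breakpoint
//        junctions of (current genome, target) -- cutting inside a maximal
//        shared block is never needed on some minimal path.
//   HT2 (lower bound):   a k-path cannot exist when
//        nb_breakpoints(X, target) > 3 * k, since one step changes at most
//        three adjacencies.
//
// A second admissible bound sharpens HT2 for distant genomes: an inversion
// is one double-cut-and-join (DCJ) operation and a (reverse) transposition
// is two, so k rearrangements perform at most 2k DCJs, while sorting X into
// the target needs exactly n - c DCJs (c = cycles of the adjacency graph of
// the two circular genomes).  Hence no k-path exists when n - c > 2k.  Like
// the breakpoint bound this can only prune branches that provably contain
// no solution, so distances and path sets are unchanged.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

namespace {

typedef std::vector<int> Gen;

// Total order on signed genes: label ascending, "+" before "-".
inline int keyof(int s) { return 2 * (s < 0 ? -s : s) + (s < 0 ? 1 : 0); }

bool key_less(const Gen& x, const Gen& y) {
  for (size_t i = 0; i < x.size(); ++i) {
    int kx = keyof(x[i]), ky = keyof(y[i]);
    if (kx != ky) return kx < ky;
  }
  return false;
}

Gen reflect(const Gen& g) {
  Gen out(g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = -g[g.size() - 1 - i];
  return out;
}

// Lexicographically least representation (2n for circular, 2 for linear).
Gen canonical_of(const Gen& g, bool circular) {
  Gen best = g;
  Gen r = reflect(g);
  if (!circular) {
    if (key_less(r, best)) best = r;
    return best;
  }
  int n = (int)g.size();
  Gen rot(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) rot[i] = g[(s + i) % n];
    if (key_less(rot, best)) best = rot;
    for (int i = 0; i < n; ++i) rot[i] = r[(s + i) % n];
    if (key_less(rot, best)) best = rot;
  }
  return best;
}

struct Move {
  // type: 0 inversion, 1 transposition, 2/3/4 reverse transposition variants
  int type, a, b, c;
  int bp;  // breakpoint count of the resulting child vs the target
};

class Engine {
public:
  int n;
  bool circular, ht1, ht2;
  std::vector<int> succ;              // target successor table, idx = s + n
  std::vector<Gen> gen;               // genome at each search depth
  std::vector<std::vector<Move>> mv;  // move buffer per depth
  std::vector<char> bpj;              // junction-is-breakpoint flags (per node)
  std::vector<int> jl;                // junction list scratch
  std::vector<int> tmatch;            // target adjacency matching on extremities
  std::vector<int> gmatch, cseen;     // per-node scratch for cycle counting
  bool collect;                       // enumerate all paths vs find one
  std::vector<std::vector<Gen>> paths;
  long long nodes;

  void init(const Gen& a, const Gen& b, bool circ, bool h1, bool h2,
            int maxdepth) {
    n = (int)a.size();
    circular = circ; ht1 = h1; ht2 = h2;
    nodes = 0;
    succ.assign(2 * n + 1, 0);
    int m = circular ? n : n - 1;
    for (int i = 0; i < m; ++i) {
      int u = b[i], v = b[(i + 1) % n];
      succ[u + n] = v;
      succ[-v + n] = -u;
    }
    gen.assign(maxdepth + 2, Gen(n));
    mv.assign(maxdepth + 2, std::vector<Move>());
    bpj.assign(n + 1, 0);
    gen[0] = a;
    if (circular) {
      tmatch.assign(2 * n, -1);
      gmatch.assign(2 * n, -1);
      cseen.assign(2 * n, 0);
      fill_match(b, tmatch);
    }
  }

  // Extremity encoding: gene g (1..n) has tail 2(g-1) and head 2(g-1)+1; a
  // signed gene +g reads tail->head, -g reads head->tail.  The adjacency
  // between successive signed genes joins the right extremity of the first
  // to the left extremity of the second.
  inline int right_ext(int s) const {
    return s > 0 ? 2 * (s - 1) + 1 : 2 * (-s - 1);
  }
  inline int left_ext(int s) const {
    return s > 0 ? 2 * (s - 1) : 2 * (-s - 1) + 1;
  }

  void fill_match(const Gen& g, std::vector<int>& m) {
    for (int i = 0; i < n; ++i) {
      int u = right_ext(g[i]), v = left_ext(g[(i + 1) % n]);
      m[u] = v;
      m[v] = u;
    }
  }

  // cycles of the adjacency graph of (g, target); n cycles iff g == target
  int cycles(const Gen& g) {
    fill_match(g, gmatch);
    std::fill(cseen.begin(), cseen.end(), 0);
    int c = 0;
    for (int e = 0; e < 2 * n; ++e) {
      if (cseen[e]) continue;
      ++c;
      int x = e;
      // alternate g-adjacency / target-adjacency edges around the cycle
      do {
        cseen[x] = 1;
        int y = gmatch[x];
        cseen[y] = 1;
        x = tmatch[y];
      } while (x != e);
    }
    return c;
  }

  inline bool dcj_dead(const Gen& g, int rem) {
    return ht2 && circular && n - cycles(g) > 2 * rem;
  }

  inline bool adj(int u, int v) const { return succ[u + n] == v; }

  int breakpoints(const Gen& g) const {
    int c = 0;
    if (circular) {
      for (int i = 0; i < n; ++i)
        if (!adj(g[i], g[(i + 1) % n])) ++c;
    } else {
      for (int i = 0; i + 1 < n; ++i)
        if (!adj(g[i], g[i + 1])) ++c;
    }
    return c;
  }

  // ---- move generation -----------------------------------------------
  // Admissible children of gen[depth] with `rem` steps left to spend.
  void gen_moves(int depth, int bp, int rem) {
    std::vector<Move>& out = mv[depth];
    out.clear();
    const Gen& g = gen[depth];
    int child_cap = (ht2 && rem > 1) ? 3 * (rem - 1) : INT_MAX;
    if (circular) gen_moves_circular(g, bp, rem, child_cap, out);
    else gen_moves_linear(g, bp, rem, child_cap, out);
  }

  inline bool keep_child(int bpc, int rem, int cap) const {
    if (rem == 1) return bpc == 0;       // last step must land on the target
    if (bpc == 0) return false;          // never revisit the target early
    return bpc <= cap;
  }

  void gen_moves_circular(const Gen& g, int bp, int rem, int cap,
                          std::vector<Move>& out) {
    for (int j = 0; j < n; ++j)
      bpj[j] = !adj(g[(j - 1 + n) % n], g[j]);

    // inversions: block spans junctions (a, b); complement gives the same
    // circular genome, so only the shorter block (ties broken by a < b).
    for (int a = 0; a < n; ++a) {
      int ea = g[(a - 1 + n) % n], sa = g[a];
      for (int l = 1; 2 * l <= n; ++l) {
        int b = (a + l) % n;
        if (2 * l == n && a > b) continue;
        if (ht1 && !(bpj[a] && bpj[b])) continue;
        int eb = g[(b - 1 + n) % n], sb = g[b];
        int bpc = bp - (bpj[a] + bpj[b]) + !adj(ea, -eb) + !adj(-sa, sb);
        if (keep_child(bpc, rem, cap)) out.push_back({0, a, b, 0, bpc});
      }
    }

    // transpositions and reverse transpositions: one unordered triple of
    // cut junctions gives 1 transposition child and 3 reverse ones.
    jl.clear();
    if (ht1) {
      for (int j = 0; j < n; ++j) if (bpj[j]) jl.push_back(j);
    } else {
      for (int j = 0; j < n; ++j) jl.push_back(j);
    }
    int m = (int)jl.size();
    for (int ia = 0; ia < m; ++ia) {
      int a = jl[ia];
      int e3 = g[(a - 1 + n) % n], s1 = g[a];
      for (int ib = ia + 1; ib < m; ++ib) {
        int b = jl[ib];
        int e1 = g[(b - 1 + n) % n], s2 = g[b];
        for (int ic = ib + 1; ic < m; ++ic) {
          int c = jl[ic];
          int e2 = g[(c - 1 + n) % n], s3 = g[c];
          int base = bp - (bpj[a] + bpj[b] + bpj[c]);
          int bpc;
          bpc = base + !adj(e2, s1) + !adj(e1, s3) + !adj(e3, s2);
          if (keep_child(bpc, rem, cap)) out.push_back({1, a, b, c, bpc});
          bpc = base + !adj(e2, -e1) + !adj(-s1, s3) + !adj(e3, s2);
          if (keep_child(bpc, rem, cap)) out.push_back({2, a, b, c, bpc});
          bpc = base + !adj(e1, s3) + !adj(e3, -e2) + !adj(-s2, s1);
          if (keep_child(bpc, rem, cap)) out.push_back({3, a, b, c, bpc});
          bpc = base + !adj(e1, -e3) + !adj(-s3, s2) + !adj(e2, s1);
          if (keep_child(bpc, rem, cap)) out.push_back({4, a, b, c, bpc});
        }
      }
    }
  }

  void gen_moves_linear(const Gen& g, int bp, int rem, int cap,
                        std::vector<Move>& out) {
    // junction j in 1..n-1 lies between positions j-1 and j; a block may be
    // detached and re-inserted at either extremity as well.
    for (int j = 1; j < n; ++j) bpj[j] = !adj(g[j - 1], g[j]);
    bpj[0] = 0;

    // inversions of block [a, b): strict block (not the whole genome).
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b <= n; ++b) {
        if (a == 0 && b == n) continue;
        if (ht1 && ((a > 0 && !bpj[a]) || (b < n && !bpj[b]))) continue;
        int removed = (a > 0 ? bpj[a] : 0) + (b < n ? bpj[b] : 0);
        int added = 0;
        if (a > 0) added += !adj(g[a - 1], -g[b - 1]);
        if (b < n) added += !adj(-g[a], g[b]);
        int bpc = bp - removed + added;
        if (keep_child(bpc, rem, cap)) out.push_back({0, a, b, 0, bpc});
      }
    }

    // boundaries 0 <= a < b < c <= n: swap adjacent blocks X=[a,b), Y=[b,c),
    // plain ([Y X]) or with one of them inverted.
    for (int a = 0; a <= n - 2; ++a) {
      if (ht1 && a > 0 && !bpj[a]) continue;
      for (int b = a + 1; b <= n - 1; ++b) {
        if (ht1 && !bpj[b]) continue;
        for (int c = b + 1; c <= n; ++c) {
          if (ht1 && c < n && !bpj[c]) continue;
          int removed = (a > 0 ? bpj[a] : 0) + bpj[b] + (c < n ? bpj[c] : 0);
          int base = bp - removed;
          int bpc;
          // [Y X]
          bpc = base + (a > 0 ? !adj(g[a - 1], g[b]) : 0)
                     + !adj(g[c - 1], g[a])
                     + (c < n ? !adj(g[b - 1], g[c]) : 0);
          if (keep_child(bpc, rem, cap)) out.push_back({1, a, b, c, bpc});
          // [Y -X]
          bpc = base + (a > 0 ? !adj(g[a - 1], g[b]) : 0)
                     + !adj(g[c - 1], -g[b - 1])
                     + (c < n ? !adj(-g[a], g[c]) : 0);
          if (keep_child(bpc, rem, cap)) out.push_back({2, a, b, c, bpc});
          // [-Y X]
          bpc = base + (a > 0 ? !adj(g[a - 1], -g[c - 1]) : 0)
                     + !adj(-g[b], g[a])
                     + (c < n ? !adj(g[b - 1], g[c]) : 0);
          if (keep_child(bpc, rem, cap)) out.push_back({3, a, b, c, bpc});
        }
      }
    }
  }

  // ---- move application ----------------------------------------------
  void apply(int depth, const Move& m) {
    const Gen& g = gen[depth];
    Gen& out = gen[depth + 1];
    if (circular) apply_circular(g, m, out);
    else apply_linear(g, m, out);
  }

  void apply_circular(const Gen& g, const Move& m, Gen& out) const {
    int p = 0;
    if (m.type == 0) {  // inversion of block [a, b)
      int a = m.a, b = m.b;
      int l = (b - a + n) % n;
      for (int t = 0; t < l; ++t) out[p++] = -g[(b - 1 - t + n) % n];
      for (int t = 0; t < n - l; ++t) out[p++] = g[(b + t) % n];
      return;
    }
    int a = m.a, b = m.b, c = m.c;
    int l1 = b - a, l2 = c - b, l3 = n - (c - a);
    switch (m.type) {
    case 1:  // (A2 A1 A3)
      for (int t = 0; t < l2; ++t) out[p++] = g[b + t];
      for (int t = 0; t < l1; ++t) out[p++] = g[a + t];
      for (int t = 0; t < l3; ++t) out[p++] = g[(c + t) % n];
      break;
    case 2:  // (A2 -A1 A3)
      for (int t = 0; t < l2; ++t) out[p++] = g[b + t];
      for (int t = 0; t < l1; ++t) out[p++] = -g[b - 1 - t];
      for (int t = 0; t < l3; ++t) out[p++] = g[(c + t) % n];
      break;
    case 3:  // (A1 A3 -A2)
      for (int t = 0; t < l1; ++t) out[p++] = g[a + t];
      for (int t = 0; t < l3; ++t) out[p++] = g[(c + t) % n];
      for (int t = 0; t < l2; ++t) out[p++] = -g[c - 1 - t];
      break;
    default:  // (A1 -A3 A2)
      for (int t = 0; t < l1; ++t) out[p++] = g[a + t];
      for (int t = 0; t < l3; ++t) out[p++] = -g[(a - 1 - t + n) % n];
      for (int t = 0; t < l2; ++t) out[p++] = g[b + t];
    }
  }

  void apply_linear(const Gen& g, const Move& m, Gen& out) const {
    int p = 0;
    int a = m.a, b = m.b, c = m.c;
    switch (m.type) {
    case 0:  // inversion of [a, b)
      for (int t = 0; t < a; ++t) out[p++] = g[t];
      for (int t = 0; t < b - a; ++t) out[p++] = -g[b - 1 - t];
      for (int t = b; t < n; ++t) out[p++] = g[t];
      break;
    case 1:  // [Y X]
      for (int t = 0; t < a; ++t) out[p++] = g[t];
      for (int t = b; t < c; ++t) out[p++] = g[t];
      for (int t = a; t < b; ++t) out[p++] = g[t];
      for (int t = c; t < n; ++t) out[p++] = g[t];
      break;
    case 2:  // [Y -X]
      for (int t = 0; t < a; ++t) out[p++] = g[t];
      for (int t = b; t < c; ++t) out[p++] = g[t];
      for (int t = 0; t < b - a; ++t) out[p++] = -g[b - 1 - t];
      for (int t = c; t < n; ++t) out[p++] = g[t];
      break;
    default:  // [-Y X]
      for (int t = 0; t < a; ++t) out[p++] = g[t];
      for (int t = 0; t < c - b; ++t) out[p++] = -g[c - 1 - t];
      for (int t = a; t < b; ++t) out[p++] = g[t];
      for (int t = c; t < n; ++t) out[p++] = g[t];
    }
  }

  // ---- search ----------------------------------------------------------
  bool dfs_one(int depth, int rem, int bp) {
    ++nodes;
    if ((nodes & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    if (bp == 0) return rem == 0;
    if (rem == 0) return false;
    if (dcj_dead(gen[depth], rem)) return false;
    gen_moves(depth, bp, rem);
    std::sort(mv[depth].begin(), mv[depth].end(),
              [](const Move& x, const Move& y) { return x.bp < y.bp; });
    // mv[depth] is consumed by index because deeper levels reuse their own
    // buffers, never this one.
    for (size_t i = 0; i < mv[depth].size(); ++i) {
      Move m = mv[depth][i];
      apply(depth, m);
      if (dfs_one(depth + 1, rem - 1, m.bp)) return true;
    }
    return false;
  }

  void dfs_all(int depth, int rem, int bp) {
    ++nodes;
    if ((nodes & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    if (bp == 0 && rem == 0) {
      std::vector<Gen> p(gen.begin(), gen.begin() + depth + 1);
      paths.push_back(p);
      return;
    }
    if (bp == 0 || rem == 0) return;
    if (ht2 && bp > 3 * rem) return;
    if (dcj_dead(gen[depth], rem)) return;
    gen_moves(depth, bp, rem);
    // children deduplicated by canonical representation: equivalent
    // operations that survive structural dedup (rare coincidences) collapse,
    // and paths become sequences of canonical genomes.
    std::vector<std::pair<Gen, int>> kids;
    kids.reserve(mv[depth].size());
    for (size_t i = 0; i < mv[depth].size(); ++i) {
      apply(depth, mv[depth][i]);
      kids.push_back(std::make_pair(canonical_of(gen[depth + 1], circular),
                                    mv[depth][i].bp));
    }
    std::sort(kids.begin(), kids.end(),
              [](const std::pair<Gen, int>& x, const std::pair<Gen, int>& y) {
                return key_less(x.first, y.first);
              });
    kids.erase(std::unique(kids.begin(), kids.end(),
                           [](const std::pair<Gen, int>& x,
                              const std::pair<Gen, int>& y) {
                             return x.first == y.first;
                           }),
               kids.end());
    for (size_t i = 0; i < kids.size(); ++i) {
      gen[depth + 1] = kids[i].first;
      dfs_all(depth + 1, rem - 1, kids[i].second);
    }
  }
};

Gen from_iv(const IntegerVector& v) {
  Gen g(v.size());
  for (int i = 0; i < v.size(); ++i) g[i] = v[i];
  return g;
}

IntegerVector to_iv(const Gen& g) {
  IntegerVector out(g.size());
  for (size_t i = 0; i < g.size(); ++i) out[i] = g[i];
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_canonical")]]
IntegerVector cpp_canonical(IntegerVector g, bool circular) {
  return to_iv(canonical_of(from_iv(g), circular));
}

// [[Rcpp::export(name = ".cpp_breakpoints")]]
int cpp_breakpoints(IntegerVector a, IntegerVector b, bool circular) {
  Engine e;
  e.init(from_iv(a), from_iv(b), circular, false, false, 1);
  return e.breakpoints(e.gen[0]);
}

// All genomes one rearrangement away, deduplicated by canonical form and
// sorted; the starting genome itself never appears.
// [[Rcpp::export(name = ".cpp_neighbors")]]
List cpp_neighbors(IntegerVector g, bool circular) {
  Gen x = from_iv(g);
  Engine e;
  e.init(x, x, circular, false, false, 1);
  // rem = 2 with ht2 off keeps every child with bpc > 0; children equal to
  // the parent (bpc == 0) are impossible for these operators anyway.
  e.gen_moves(0, e.breakpoints(x), 2);
  std::vector<Gen> kids;
  kids.reserve(e.mv[0].size());
  for (size_t i = 0; i < e.mv[0].size(); ++i) {
    e.apply(0, e.mv[0][i]);
    kids.push_back(canonical_of(e.gen[1], circular));
  }
  std::sort(kids.begin(), kids.end(), key_less);
  kids.erase(std::unique(kids.begin(), kids.end()), kids.end());
  List out(kids.size());
  for (size_t i = 0; i < kids.size(); ++i) out[i] = to_iv(kids[i]);
  return out;
}

// Exact minimal distance by iterative deepening; -1 when d > kmax.
// [[Rcpp::export(name = ".cpp_distance")]]
int cpp_distance(IntegerVector a, IntegerVector b, int kmax, bool ht1,
                 bool ht2, bool circular) {
  Gen ga = from_iv(a), gb = from_iv(b);
  Engine e;
  e.init(ga, gb, circular, ht1, ht2, kmax + 1);
  int bp0 = e.breakpoints(ga);
  if (bp0 == 0) return 0;
  int kstart = ht2 ? (bp0 + 2) / 3 : 1;
  if (ht2 && circular) {
    int n = (int)ga.size();
    int kdcj = (n - e.cycles(ga) + 1) / 2;
    if (kdcj > kstart) kstart = kdcj;
  }
  if (kstart < 1) kstart = 1;
  for (int k = kstart; k <= kmax; ++k) {
    if (e.dfs_one(0, k, bp0)) return k;
  }
  return -1;
}

// Every path of length exactly k from a to b, as (k+1) x n matrices of
// canonical representations.
// [[Rcpp::export(name = ".cpp_k_paths")]]
List cpp_k_paths(IntegerVector a, IntegerVector b, int k, bool ht1, bool ht2,
                 bool circular) {
  Gen ga = canonical_of(from_iv(a), circular), gb = from_iv(b);
  Engine e;
  e.init(ga, gb, circular, ht1, ht2, k + 1);
  int bp0 = e.breakpoints(ga);
  e.paths.clear();
  e.dfs_all(0, k, bp0);
  int n = (int)ga.size();
  List out(e.paths.size());
  for (size_t i = 0; i < e.paths.size(); ++i) {
    IntegerMatrix m(k + 1, n);
    for (int r = 0; r <= k; ++r)
      for (int c = 0; c < n; ++c) m(r, c) = e.paths[i][r][c];
    out[i] = m;
  }
  return out;
}
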