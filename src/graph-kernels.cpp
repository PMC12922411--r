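// Compiled kernels for the molecular-graph layer: canonical atom ranking
// (iterative refinement + backtracking over residual symmetry) and
// subgraph-isomorphism matching. Graphs arrive as flat integer vectors;
// atom property codes are prepared on the R side. NA-like "unconstrained"
// query properties are encoded as negative sentinels.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<int> elem;    // element code; 0 = wildcard
  std::vector<int> arom;    // 1/0; -1 = unconstrained
  std::vector<int> charge;  // formal charge; -999 = unconstrained
  std::vector<int> hcount;  // total H; -1 = unconstrained
  std::vector<std::vector<int>> adj;
  std::vector<std::vector<int>> bord;  // parallel bond orders (1/2/3, 4=aromatic,
                                       // 0=single-or-aromatic, 9=any)
};

Graph from_r(IntegerVector elem, IntegerVector arom, IntegerVector charge,
             IntegerVector hcount, IntegerMatrix bond) {
  Graph g;
  g.n = elem.size();
  g.elem.assign(elem.begin(), elem.end());
  g.arom.assign(arom.begin(), arom.end());
  g.charge.assign(charge.begin(), charge.end());
  g.hcount.assign(hcount.begin(), hcount.end());
  g.adj.resize(g.n);
  g.bord.resize(g.n);
  for (int k = 0; k < bond.nrow(); ++k) {
    int a = bond(k, 0) - 1, b = bond(k, 1) - 1, o = bond(k, 2);
    g.adj[a].push_back(b); g.bord[a].push_back(o);
    g.adj[b].push_back(a); g.bord[b].push_back(o);
  }
  return g;
}

// dense ranks (1-based) of lexicographically ordered composite keys
std::vector<int> dense_ranks(std::vector<std::vector<int>>& keys) {
  int n = keys.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return keys[a] < keys[b]; });
  std::vector<int> ranks(n);
  int r = 1;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && keys[idx[i]] != keys[idx[i - 1]]) ++r;
    ranks[idx[i]] = r;
  }
  return ranks;
}

int max_rank(const std::vector<int>& ranks) {
  int m = 0;
  for (int r : ranks) m = std::max(m, r);
  return m;
}

std::vector<int> refine(const Graph& g, std::vector<int> ranks) {
  int n = g.n;
  while (true) {
    std::vector<std::vector<int>> keys(n);
    for (int i = 0; i < n; ++i) {
      std::vector<int> nb;
      nb.reserve(g.adj[i].size());
      for (size_t k = 0; k < g.adj[i].size(); ++k)
        nb.push_back(g.bord[i][k] * 10000 + ranks[g.adj[i][k]]);
      std::sort(nb.begin(), nb.end());
      keys[i].push_back(ranks[i]);
      keys[i].insert(keys[i].end(), nb.begin(), nb.end());
    }
    std::vector<int> next = dense_ranks(keys);
    if (next == ranks || max_rank(next) == n) return next;
    ranks = next;
  }
}

std::vector<int> initial_ranks(const Graph& g) {
  std::vector<std::vector<int>> keys(g.n);
  for (int i = 0; i < g.n; ++i) {
    keys[i] = {g.elem[i], g.arom[i], g.charge[i], g.hcount[i],
               (int)g.adj[i].size()};
  }
  return dense_ranks(keys);
}

// serialization of a fully-discrete labelling, for symmetry tie-breaking
std::vector<int> adjacency_code(const Graph& g, const std::vector<int>& ranks) {
  int n = g.n;
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[ranks[i] - 1] = i;
  std::vector<int> code;
  code.reserve(n * 6);
  for (int r = 0; r < n; ++r) {
    int i = pos[r];
    code.push_back(g.elem[i]);
    code.push_back(g.arom[i]);
    code.push_back(g.charge[i]);
    code.push_back(g.hcount[i]);
    std::vector<int> nb;
    for (size_t k = 0; k < g.adj[i].size(); ++k)
      nb.push_back(ranks[g.adj[i][k]] * 100 + g.bord[i][k]);
    std::sort(nb.begin(), nb.end());
    code.insert(code.end(), nb.begin(), nb.end());
    code.push_back(-1);
  }
  return code;
}

void canon_search(const Graph& g, std::vector<int> ranks,
                  std::vector<int>& best, std::vector<int>& best_code,
                  bool& have_best) {
  int n = g.n;
  if (max_rank(ranks) == n) {
    std::vector<int> code = adjacency_code(g, ranks);
    if (!have_best || code < best_code) {
      best_code = std::move(code);
      best = ranks;
      have_best = true;
    }
    return;
  }
  // smallest tied rank value
  std::vector<int> count(n + 1, 0);
  for (int r : ranks) ++count[r];
  int tied = 0;
  for (int r = 1; r <= n; ++r)
    if (count[r] > 1) { tied = r; break; }
  for (int a = 0; a < n; ++a) {
    if (ranks[a] != tied) continue;
    std::vector<int> r2 = ranks;
    for (int i = 0; i < n; ++i)
      if (r2[i] >= tied) ++r2[i];
    r2[a] = tied;
    std::vector<std::vector<int>> keys(n);
    for (int i = 0; i < n; ++i) keys[i] = {r2[i]};
    canon_search(g, refine(g, dense_ranks(keys)), best, best_code, have_best);
  }
}

bool atom_compatible(const Graph& q, int qi, const Graph& t, int ti) {
  if (q.elem[qi] != 0 && q.elem[qi] != t.elem[ti]) return false;
  if (q.arom[qi] >= 0 && q.arom[qi] != t.arom[ti]) return false;
  if (q.charge[qi] != -999 && q.charge[qi] != t.charge[ti]) return false;
  if (q.hcount[qi] >= 0 && q.hcount[qi] != t.hcount[ti]) return false;
  return true;
}

bool bond_compatible(int qo, int to) {
  if (qo == 9) return true;
  if (qo == 0) return to == 1 || to == 4;
  return qo == to;
}

struct Matcher {
  const Graph& q;
  const Graph& t;
  std::vector<int> order, anchor;  // query visit order; anchor[-1] = none
  std::vector<int> mapping;        // query -> target (-1 unmapped)
  std::vector<char> used;

  Matcher(const Graph& q_, const Graph& t_) : q(q_), t(t_) {
    int n = q.n;
    std::vector<char> placed(n, 0);
    int start = 0;
    for (int i = 1; i < n; ++i)
      if (q.adj[i].size() > q.adj[start].size()) start = i;
    order.push_back(start);
    anchor.push_back(-1);
    placed[start] = 1;
    // BFS so every later atom has a placed neighbour (queries are connected)
    for (size_t h = 0; h < order.size() && (int)order.size() < n; ++h) {
      int a = order[h];
      for (int b : q.adj[a]) {
        if (!placed[b]) {
          placed[b] = 1;
          order.push_back(b);
          anchor.push_back(a);
        }
      }
    }
    mapping.assign(n, -1);
    used.assign(t.n, 0);
  }

  bool place(size_t step) {
    if (step == order.size()) return true;
    int qi = order[step];
    int anc = anchor[step];
    if (anc < 0) {
      for (int ti = 0; ti < t.n; ++ti)
        if (try_atom(step, qi, ti)) return true;
    } else {
      int tanc = mapping[anc];
      for (int ti : t.adj[tanc])
        if (try_atom(step, qi, ti)) return true;
    }
    return false;
  }

  bool try_atom(size_t step, int qi, int ti) {
    if (used[ti]) return false;
    if (!atom_compatible(q, qi, t, ti)) return false;
    for (size_t k = 0; k < q.adj[qi].size(); ++k) {
      int qn = q.adj[qi][k];
      if (mapping[qn] < 0) continue;
      int tn = mapping[qn];
      bool found = false;
      for (size_t m = 0; m < t.adj[ti].size(); ++m) {
        if (t.adj[ti][m] == tn) {
          found = bond_compatible(q.bord[qi][k], t.bord[ti][m]);
          break;
        }
      }
      if (!found) return false;
    }
    mapping[qi] = ti;
    used[ti] = 1;
    if (place(step + 1)) return true;
    mapping[qi] = -1;
    used[ti] = 0;
    return false;
  }
};

}  // namespace

std::vector<int> canon_ranks_impl(const Graph& g) {
  if (g.n == 1) return {1};
  std::vector<int> ranks = refine(g, initial_ranks(g));
  if (max_rank(ranks) == g.n) return ranks;
  std::vector<int> best, best_code;
  bool have_best = false;
  canon_search(g, ranks, best, best_code, have_best);
  return best;
}

// [[Rcpp::export(name = ".canon_ranks_cpp")]]
IntegerVector canon_ranks_cpp(IntegerVector elem, IntegerVector arom,
                              IntegerVector charge, IntegerVector hcount,
                              IntegerMatrix bond) {
  Graph g = from_r(elem, arom, charge, hcount, bond);
  return wrap(canon_ranks_impl(g));
}

// canonical identity key: serialized adjacency code of the canonical
// labelling; equal keys <=> isomorphic graphs (within the property model)
// [[Rcpp::export(name = ".canon_key_cpp")]]
String canon_key_cpp(IntegerVector elem, IntegerVector arom,
                     IntegerVector charge, IntegerVector hcount,
                     IntegerMatrix bond) {
  Graph g = from_r(elem, arom, charge, hcount, bond);
  std::vector<int> ranks = canon_ranks_impl(g);
  std::vector<int> code = adjacency_code(g, ranks);
  std::string out;
  out.reserve(code.size() * 4);
  char buf[16];
  for (int v : code) {
    snprintf(buf, sizeof(buf), "%d,", v);
    out += buf;
  }
  return String(out);
}

// [[Rcpp::export(name = ".match_exists_cpp")]]
bool match_exists_cpp(IntegerVector q_elem, IntegerVector q_arom,
                      IntegerVector q_charge, IntegerVector q_hcount,
                      IntegerMatrix q_bond, IntegerVector t_elem,
                      IntegerVector t_arom, IntegerVector t_charge,
                      IntegerVector t_hcount, IntegerMatrix t_bond) {
  Graph q = from_r(q_elem, q_arom, q_charge, q_hcount, q_bond);
  Graph t = from_r(t_elem, t_arom, t_charge, t_hcount, t_bond);
  if (q.n > t.n) return false;
  Matcher m(q, t);
  return m.place(0);
}
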