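// Graph kernels for the de Bruijn graph D_k on sigma^k k-mers.
//
// K-mers are big-endian base-sigma integer codes in [0, sigma^k).
// Edges: u -> (u mod sigma^(k-1)) * sigma + b for b in 0..sigma-1.
// All routines are iterative (explicit stacks / Kahn peeling); no
// recursion-depth dependence except Johnson's enumeration, which is
// gated to tiny graphs by the caller.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstring>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Space {
  int sigma, k, W, N;  // W = sigma^(k-1), N = sigma^k
};

Space make_space(int sigma, int k) {
  if (sigma < 2) stop("sigma must be >= 2");
  if (k < 2) stop("k must be >= 2");
  long long w = 1;
  for (int i = 0; i < k - 1; ++i) {
    w *= sigma;
    if (w > INT_MAX) stop("sigma^k exceeds integer range");
  }
  long long n = w * sigma;
  if (n > INT_MAX) stop("sigma^k exceeds integer range");
  Space sp;
  sp.sigma = sigma;
  sp.k = k;
  sp.W = static_cast<int>(w);
  sp.N = static_cast<int>(n);
  return sp;
}

inline int succ_code(int u, const Space& sp, int b) {
  return (u % sp.W) * sp.sigma + b;
}

inline int pred_code(int u, const Space& sp, int b) {
  return b * sp.W + u / sp.sigma;
}

// Longest path in vertex counts over the subgraph induced by rem[u] == 1.
// Returns -1 if the subgraph has a directed cycle. Witness path (codes in
// order) optionally written to *witness.
int longest_path_vertices(const std::vector<char>& rem, const Space& sp,
                          std::vector<int>* witness) {
  std::vector<int> indeg(sp.N, 0);
  int alive = 0;
  for (int u = 0; u < sp.N; ++u) {
    if (!rem[u]) continue;
    ++alive;
    for (int b = 0; b < sp.sigma; ++b) {
      int v = succ_code(u, sp, b);
      if (rem[v]) ++indeg[v];
    }
  }
  if (alive == 0) {
    if (witness) witness->clear();
    return 0;
  }
  std::vector<int> order;
  order.reserve(alive);
  std::vector<int> stack;
  for (int u = 0; u < sp.N; ++u)
    if (rem[u] && indeg[u] == 0) stack.push_back(u);
  std::vector<int> dp(sp.N, 0), par(sp.N, -1);
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    order.push_back(u);
    if (dp[u] == 0) dp[u] = 1;
    for (int b = 0; b < sp.sigma; ++b) {
      int v = succ_code(u, sp, b);
      if (!rem[v]) continue;
      if (dp[u] + 1 > dp[v]) {
        dp[v] = dp[u] + 1;
        par[v] = u;
      }
      if (--indeg[v] == 0) stack.push_back(v);
    }
  }
  if (static_cast<int>(order.size()) != alive) return -1;  // cycle
  int best = 0, argbest = -1;
  for (int u : order)
    if (dp[u] > best) {
      best = dp[u];
      argbest = u;
    }
  if (witness) {
    witness->clear();
    for (int u = argbest; u != -1; u = par[u]) witness->push_back(u);
    std::reverse(witness->begin(), witness->end());
  }
  return best;
}

std::vector<char> complement_mask(const std::vector<int>& members,
                                  const Space& sp) {
  std::vector<char> rem(sp.N, 1);
  for (int m : members) {
    if (m < 0 || m >= sp.N) stop("k-mer code out of range");
    rem[m] = 0;
  }
  return rem;
}

std::string set_key(const std::vector<int>& m) {
  std::string s(m.size() * sizeof(int), '\0');
  if (!m.empty()) std::memcpy(&s[0], m.data(), s.size());
  return s;
}

}  // namespace

// [[Rcpp::export]]
bool cpp_is_decycling(IntegerVector members, int sigma, int k) {
  Space sp = make_space(sigma, k);
  std::vector<int> mem(members.begin(), members.end());
  std::vector<char> rem = complement_mask(mem, sp);
  return longest_path_vertices(rem, sp, nullptr) >= 0;
}

// [[Rcpp::export]]
List cpp_longest_path(IntegerVector members, int sigma, int k) {
  Space sp = make_space(sigma, k);
  std::vector<int> mem(members.begin(), members.end());
  std::vector<char> rem = complement_mask(mem, sp);
  std::vector<int> wit;
  int L = longest_path_vertices(rem, sp, &wit);
  if (L < 0) stop("graph has a cycle");
  return List::create(_["vertices"] = L,
                      _["path"] = IntegerVector(wit.begin(), wit.end()));
}

// Exhaustive scan of PCR sets (one member per orbit) for decycling sets.
// orbits: list of integer vectors (member codes, ascending), ordered by
// their smallest member. Returns a matrix with one MDS per row (sorted
// codes), rows in odometer order (first orbit varies slowest).
// [[Rcpp::export]]
IntegerMatrix cpp_brute_force_mds(List orbits, int sigma, int k) {
  Space sp = make_space(sigma, k);
  int no = orbits.size();
  std::vector<std::vector<int>> orb(no);
  for (int i = 0; i < no; ++i) {
    IntegerVector o = orbits[i];
    orb[i].assign(o.begin(), o.end());
  }
  std::vector<int> idx(no, 0), chosen(no);
  std::vector<std::vector<int>> found;
  std::vector<char> rem(sp.N);
  bool done = false;
  while (!done) {
    std::fill(rem.begin(), rem.end(), 1);
    for (int i = 0; i < no; ++i) {
      chosen[i] = orb[i][idx[i]];
      rem[chosen[i]] = 0;
    }
    if (longest_path_vertices(rem, sp, nullptr) >= 0) {
      std::vector<int> mds(chosen);
      std::sort(mds.begin(), mds.end());
      found.push_back(std::move(mds));
    }
    // odometer: last orbit varies fastest
    int pos = no - 1;
    while (pos >= 0) {
      if (++idx[pos] < static_cast<int>(orb[pos].size())) break;
      idx[pos] = 0;
      --pos;
    }
    if (pos < 0) done = true;
  }
  int nr = found.size(), nc = no;
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) out(i, j) = found[i][j];
  return out;
}

// Layer-by-layer closure of an MDS under F-moves (one strongly connected
// component of the MDS graph, by the component-structure proposition).
// Keeps two resident layers plus a visited-key ledger; checks the
// sigma^(k-1)-partite layer closure on every cross edge.
// [[Rcpp::export]]
List cpp_enumerate_component(IntegerVector m0, int sigma, int k,
                             bool want_members, bool want_rpl) {
  Space sp = make_space(sigma, k);
  std::vector<int> start(m0.begin(), m0.end());
  std::sort(start.begin(), start.end());
  size_t msize = start.size();

  std::unordered_map<std::string, int> layer_of;
  std::vector<double> layer_sizes(sp.W, 0.0);
  std::vector<std::vector<int>> members;
  std::vector<int> rep = start;
  int rplmin = INT_MAX, rplmax = -1;
  double total = 0;

  std::vector<std::vector<int>> cur, nxt;
  cur.push_back(start);
  layer_of[set_key(start)] = 0;
  int wave = 0;
  std::vector<char> inM(sp.N), rem(sp.N), child_mask(sp.N);

  while (!cur.empty()) {
    int lay = wave % sp.W;
    for (std::vector<int>& M : cur) {
      total += 1;
      layer_sizes[lay] += 1;
      if (M < rep) rep = M;
      std::fill(inM.begin(), inM.end(), 0);
      for (int c : M) inM[c] = 1;
      if (want_rpl) {
        for (int u = 0; u < sp.N; ++u) rem[u] = !inM[u];
        int L = longest_path_vertices(rem, sp, nullptr);
        if (L < 0) stop("component member is not decycling");
        rplmin = std::min(rplmin, L);
        rplmax = std::max(rplmax, L);
      }
      if (want_members) members.push_back(M);
      for (int f = 0; f < sp.W; ++f) {
        bool valid = true;
        for (int a = 0; a < sp.sigma && valid; ++a)
          if (!inM[a * sp.W + f]) valid = false;
        if (!valid) continue;
        std::copy(inM.begin(), inM.end(), child_mask.begin());
        for (int a = 0; a < sp.sigma; ++a) child_mask[a * sp.W + f] = 0;
        for (int b = 0; b < sp.sigma; ++b) child_mask[f * sp.sigma + b] = 1;
        std::vector<int> child;
        child.reserve(msize);
        for (int u = 0; u < sp.N; ++u)
          if (child_mask[u]) child.push_back(u);
        std::string ck = set_key(child);
        int clay = (lay + 1) % sp.W;
        auto it = layer_of.find(ck);
        if (it == layer_of.end()) {
          layer_of.emplace(std::move(ck), clay);
          nxt.push_back(std::move(child));
        } else if (it->second != clay) {
          stop("layer closure violated: component is not sigma^(k-1)-partite");
        }
      }
    }
    cur.swap(nxt);
    nxt.clear();
    ++wave;
  }

  List out = List::create(
      _["size"] = total,
      _["layer_sizes"] = NumericVector(layer_sizes.begin(), layer_sizes.end()),
      _["rpl_min"] = want_rpl ? rplmin : NA_INTEGER,
      _["rpl_max"] = want_rpl ? rplmax : NA_INTEGER,
      _["representative"] = IntegerVector(rep.begin(), rep.end()));
  if (want_members) {
    IntegerMatrix mm(members.size(), msize);
    for (size_t i = 0; i < members.size(); ++i)
      for (size_t j = 0; j < msize; ++j) mm(i, j) = members[i][j];
    out["members"] = mm;
  }
  return out;
}

// Constrained-cycle discovery of the component's full I-move list from a
// single member MDS. A constrained cycle hits M exactly once; an I-move
// f|m is invalid throughout the component iff some constrained cycle uses
// an edge af -> fb with bit a set and bit b clear. Runtime O(|M| N sigma),
// independent of component size.
// [[Rcpp::export]]
IntegerMatrix cpp_component_imoves(IntegerVector m, int sigma, int k) {
  Space sp = make_space(sigma, k);
  std::vector<int> mem(m.begin(), m.end());
  std::vector<char> inM(sp.N, 0);
  for (int c : mem) {
    if (c < 0 || c >= sp.N) stop("k-mer code out of range");
    inM[c] = 1;
  }
  // tag[u * sigma + b]: edge u -> succ(u, b) lies on a constrained cycle
  std::vector<char> tag(static_cast<size_t>(sp.N) * sp.sigma, 0);
  std::vector<char> fwd(sp.N), bwd(sp.N);
  std::vector<int> stack;
  for (int x : mem) {
    // forward: nodes not in M reachable from x through nodes not in M
    std::fill(fwd.begin(), fwd.end(), 0);
    for (int b = 0; b < sp.sigma; ++b) {
      int v = succ_code(x, sp, b);
      if (!inM[v] && !fwd[v]) {
        fwd[v] = 1;
        stack.push_back(v);
      }
    }
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int b = 0; b < sp.sigma; ++b) {
        int v = succ_code(u, sp, b);
        if (!inM[v] && !fwd[v]) {
          fwd[v] = 1;
          stack.push_back(v);
        }
      }
    }
    // backward: nodes not in M that reach x through nodes not in M
    std::fill(bwd.begin(), bwd.end(), 0);
    for (int b = 0; b < sp.sigma; ++b) {
      int v = pred_code(x, sp, b);
      if (!inM[v] && !bwd[v]) {
        bwd[v] = 1;
        stack.push_back(v);
      }
    }
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int b = 0; b < sp.sigma; ++b) {
        int v = pred_code(u, sp, b);
        if (!inM[v] && !bwd[v]) {
          bwd[v] = 1;
          stack.push_back(v);
        }
      }
    }
    // tag edges u -> v with u in {x} u fwd, v in {x} u bwd
    for (int u = 0; u < sp.N; ++u) {
      if (u != x && !fwd[u]) continue;
      for (int b = 0; b < sp.sigma; ++b) {
        int v = succ_code(u, sp, b);
        if (v == x || bwd[v]) tag[static_cast<size_t>(u) * sp.sigma + b] = 1;
      }
    }
  }

  int full = (1 << sp.sigma) - 1;
  std::vector<int> fs, masks;
  for (int f = 0; f < sp.W; ++f) {
    // homopolymer word a^(k-1)? its letter's bit is pinned to 1 and the
    // shared k-mer a^k is never moved.
    int rep1 = (sp.W - 1) / (sp.sigma - 1);  // code of 1^(k-1)
    int hom = (f % rep1 == 0 && f / rep1 < sp.sigma) ? f / rep1 : -1;
    for (int mask = 1; mask < full; ++mask) {
      if (hom >= 0) {
        if (!(mask & (1 << hom))) continue;  // bit pinned to 1
        int rest = mask & ~(1 << hom);
        if (rest == 0 || rest == (full & ~(1 << hom)))
          continue;  // need a mixture among the other letters
      }
      bool bad = false;
      for (int a = 0; a < sp.sigma && !bad; ++a) {
        if (!(mask & (1 << a)) || a == hom) continue;  // only moved letters
        int af = a * sp.W + f;
        for (int b = 0; b < sp.sigma && !bad; ++b) {
          if (mask & (1 << b)) continue;
          if (tag[static_cast<size_t>(af) * sp.sigma + b]) bad = true;
        }
      }
      if (!bad) {
        fs.push_back(f);
        masks.push_back(mask);
      }
    }
  }
  IntegerMatrix out(fs.size(), 2);
  for (size_t i = 0; i < fs.size(); ++i) {
    out(i, 0) = fs[i];
    out(i, 1) = masks[i];
  }
  colnames(out) = CharacterVector::create("f", "mask");
  return out;
}

// First row (1-based) of the member matrix (one MDS per row, codes sorted
// ascending) in which the I-move f|mask is valid; 0 when none is. For a
// homopolymer word the pinned letter is skipped (its k-mer stays put).
// [[Rcpp::export]]
int cpp_find_host(IntegerMatrix members, int sigma, int k, int f, int mask) {
  Space sp = make_space(sigma, k);
  int rep1 = (sp.W - 1) / (sp.sigma - 1);
  int hom = (f % rep1 == 0 && f / rep1 < sp.sigma) ? f / rep1 : -1;
  int nr = members.nrow(), nc = members.ncol();
  for (int i = 0; i < nr; ++i) {
    bool ok = true;
    for (int a = 0; a < sp.sigma && ok; ++a) {
      if (a == hom) continue;
      int af = a * sp.W + f, fa = f * sp.sigma + a;
      bool has_af = false, has_fa = false;
      for (int j = 0; j < nc; ++j) {
        int c = members(i, j);
        if (c == af) has_af = true;
        if (c == fa) has_fa = true;
        if (c > af && c > fa) break;
      }
      if (mask & (1 << a)) ok = has_af && !has_fa;
      else ok = has_fa && !has_af;
    }
    if (ok) return i + 1;
  }
  return 0;
}

namespace {

// Johnson-style simple-cycle enumeration state (explicit recursion since
// graphs are tiny: caller gates N).
struct JohnsonState {
  const Space* sp;
  int s;
  std::vector<char> blocked;
  std::vector<std::vector<int>> B;
  std::vector<int> path;
  std::vector<std::vector<int>>* out;
  R_xlen_t max_cycles;
};

void unblock(JohnsonState& st, int u) {
  st.blocked[u] = 0;
  for (size_t i = 0; i < st.B[u].size(); ++i) {
    int w = st.B[u][i];
    if (st.blocked[w]) unblock(st, w);
  }
  st.B[u].clear();
}

bool circuit(JohnsonState& st, int v) {
  bool found = false;
  st.path.push_back(v);
  st.blocked[v] = 1;
  for (int b = 0; b < st.sp->sigma; ++b) {
    int w = succ_code(v, *st.sp, b);
    if (w < st.s) continue;
    if (w == st.s) {
      if (static_cast<R_xlen_t>(st.out->size()) >= st.max_cycles)
        stop("cycle enumeration limit exceeded");
      st.out->push_back(st.path);
      found = true;
    } else if (!st.blocked[w]) {
      if (circuit(st, w)) found = true;
    }
  }
  if (found) {
    unblock(st, v);
  } else {
    for (int b = 0; b < st.sp->sigma; ++b) {
      int w = succ_code(v, *st.sp, b);
      if (w < st.s) continue;
      std::vector<int>& lst = st.B[w];
      if (std::find(lst.begin(), lst.end(), v) == lst.end()) lst.push_back(v);
    }
  }
  st.path.pop_back();
  return found;
}

}  // namespace

// All simple directed cycles of D_k, each reported starting at its
// smallest node. Caller gates sigma^k; max_cycles is a hard cap.
// [[Rcpp::export]]
List cpp_simple_cycles(int sigma, int k, double max_cycles) {
  Space sp = make_space(sigma, k);
  std::vector<std::vector<int>> cycles;
  JohnsonState st;
  st.sp = &sp;
  st.out = &cycles;
  st.max_cycles = static_cast<R_xlen_t>(max_cycles);
  for (int s = 0; s < sp.N; ++s) {
    st.s = s;
    st.blocked.assign(sp.N, 0);
    st.B.assign(sp.N, std::vector<int>());
    st.path.clear();
    circuit(st, s);
  }
  List out(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i)
    out[i] = IntegerVector(cycles[i].begin(), cycles[i].end());
  return out;
}
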