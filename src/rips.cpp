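#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 over GF(2).
//
// Simplices (vertices, edges, triangles) enter at the maximum pairwise
// distance among their vertices and are globally ordered by
// (filtration value, dimension, lexicographic vertex tuple), which puts
// every face before its cofaces and makes diagrams deterministic across
// platforms. Reduction uses the twist ("clearing") optimisation: triangle
// columns are reduced first, so edge columns they pair with are skipped,
// and the remaining dimension-0 pairing is done by union-find with the
// elder rule (equivalent to standard column reduction for dimension 0).
// Reduced triangle columns are kept: the column that kills an H1 class is
// its representative cycle.

struct Simp {
  double value;
  int dim;
  int a, b, c; // 0-based vertex ids, ascending; unused slots = -1
};

static bool simp_less(const Simp &x, const Simp &y) {
  if (x.value != y.value) return x.value < y.value;
  if (x.dim != y.dim) return x.dim < y.dim;
  if (x.a != y.a) return x.a < y.a;
  if (x.b != y.b) return x.b < y.b;
  return x.c < y.c;
}

static std::vector<Simp> build_simplices(const NumericMatrix &d,
                                         double max_scale) {
  const int n = d.nrow();
  std::vector<Simp> s;
  s.reserve(static_cast<size_t>(n) * 4);
  for (int i = 0; i < n; ++i) s.push_back({0.0, 0, i, -1, -1});
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (d(i, j) <= max_scale) s.push_back({d(i, j), 1, i, j, -1});
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dij = d(i, j);
      if (dij > max_scale) continue;
      for (int k = j + 1; k < n; ++k) {
        double v = std::max(dij, std::max(d(i, k), d(j, k)));
        if (v <= max_scale) s.push_back({v, 2, i, j, k});
      }
    }
  std::sort(s.begin(), s.end(), simp_less);
  return s;
}

// [[Rcpp::export]]
DataFrame cpp_build_filtration(NumericMatrix d, double max_scale) {
  std::vector<Simp> s = build_simplices(d, max_scale);
  const int m = s.size();
  NumericVector value(m);
  IntegerVector dim(m), v1(m), v2(m), v3(m);
  for (int i = 0; i < m; ++i) {
    value[i] = s[i].value;
    dim[i] = s[i].dim;
    v1[i] = s[i].a + 1;
    v2[i] = s[i].b >= 0 ? s[i].b + 1 : NA_INTEGER;
    v3[i] = s[i].c >= 0 ? s[i].c + 1 : NA_INTEGER;
  }
  return DataFrame::create(_["order"] = seq_len(m), _["value"] = value,
                           _["dim"] = dim, _["v1"] = v1, _["v2"] = v2,
                           _["v3"] = v3);
}

// symmetric difference of two ascending index vectors (GF(2) addition)
static std::vector<int> symdiff(const std::vector<int> &x,
                                const std::vector<int> &y) {
  std::vector<int> out;
  out.reserve(x.size() + y.size());
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] < y[j]) out.push_back(x[i++]);
    else if (y[j] < x[i]) out.push_back(y[j++]);
    else { ++i; ++j; }
  }
  while (i < x.size()) out.push_back(x[i++]);
  while (j < y.size()) out.push_back(y[j++]);
  return out;
}

// [[Rcpp::export]]
List cpp_rips_persistence(NumericMatrix d, double max_scale) {
  const int n = d.nrow();
  std::vector<Simp> s = build_simplices(d, max_scale);
  const int m = s.size();

  // edge global index lookup
  std::unordered_map<long long, int> edge_idx;
  edge_idx.reserve(m);
  for (int i = 0; i < m; ++i)
    if (s[i].dim == 1)
      edge_idx[(long long)s[i].a * n + s[i].b] = i;

  // --- dimension-2 reduction (kills H1 classes) ---
  std::unordered_map<int, std::vector<int> > col_by_pivot;
  std::unordered_map<int, int> killer_of; // pivot edge -> triangle index
  for (int t = 0; t < m; ++t) {
    if (s[t].dim != 2) continue;
    std::vector<int> col(3);
    col[0] = edge_idx[(long long)s[t].a * n + s[t].b];
    col[1] = edge_idx[(long long)s[t].a * n + s[t].c];
    col[2] = edge_idx[(long long)s[t].b * n + s[t].c];
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      std::unordered_map<int, std::vector<int> >::iterator it =
          col_by_pivot.find(low);
      if (it == col_by_pivot.end()) {
        col_by_pivot[low] = col;
        killer_of[low] = t;
        break;
      }
      col = symdiff(col, it->second);
    }
  }

  // --- dimension-1 pairing (H0) by union-find with elder rule ---
  std::vector<int> parent(n), birthv(n);
  for (int i = 0; i < n; ++i) { parent[i] = i; birthv[i] = i; }
  // iterative find with path halving
  struct UF {
    std::vector<int> &p;
    UF(std::vector<int> &p_) : p(p_) {}
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } uf(parent);

  std::vector<double> bar_birth, bar_death;
  std::vector<int> bar_dim, bar_b1, bar_b2, bar_b3, bar_d1, bar_d2, bar_d3,
      bar_cycle;
  List cycles;
  std::vector<IntegerMatrix> cycle_store;

  int n_h0_zero = 0, n_h1_zero = 0;

  for (int e = 0; e < m; ++e) {
    if (s[e].dim != 1) continue;
    int ra = uf.find(s[e].a), rb = uf.find(s[e].b);
    if (ra != rb) {
      // merge; the younger component (larger birth vertex) dies
      int ba = birthv[ra], bb = birthv[rb];
      int dying = std::max(ba, bb), surviving = std::min(ba, bb);
      parent[ra] = rb;
      birthv[uf.find(rb)] = surviving;
      if (s[e].value > 0.0) {
        bar_dim.push_back(0);
        bar_birth.push_back(0.0);
        bar_death.push_back(s[e].value);
        bar_b1.push_back(dying + 1);
        bar_b2.push_back(NA_INTEGER);
        bar_b3.push_back(NA_INTEGER);
        bar_d1.push_back(s[e].a + 1);
        bar_d2.push_back(s[e].b + 1);
        bar_d3.push_back(NA_INTEGER);
        bar_cycle.push_back(NA_INTEGER);
      } else {
        ++n_h0_zero;
      }
    } else {
      // cycle-creating edge: killed by a triangle (finite H1) or not
      std::unordered_map<int, int>::iterator kit = killer_of.find(e);
      if (kit == killer_of.end()) {
        bar_dim.push_back(1);
        bar_birth.push_back(s[e].value);
        bar_death.push_back(R_PosInf);
        bar_b1.push_back(s[e].a + 1);
        bar_b2.push_back(s[e].b + 1);
        bar_b3.push_back(NA_INTEGER);
        bar_d1.push_back(NA_INTEGER);
        bar_d2.push_back(NA_INTEGER);
        bar_d3.push_back(NA_INTEGER);
        bar_cycle.push_back(NA_INTEGER);
      } else {
        int t = kit->second;
        if (s[t].value > s[e].value) {
          const std::vector<int> &col = col_by_pivot[e];
          IntegerMatrix cyc(col.size(), 2);
          for (size_t q = 0; q < col.size(); ++q) {
            cyc(q, 0) = s[col[q]].a + 1;
            cyc(q, 1) = s[col[q]].b + 1;
          }
          cycle_store.push_back(cyc);
          bar_dim.push_back(1);
          bar_birth.push_back(s[e].value);
          bar_death.push_back(s[t].value);
          bar_b1.push_back(s[e].a + 1);
          bar_b2.push_back(s[e].b + 1);
          bar_b3.push_back(NA_INTEGER);
          bar_d1.push_back(s[t].a + 1);
          bar_d2.push_back(s[t].b + 1);
          bar_d3.push_back(s[t].c + 1);
          bar_cycle.push_back(cycle_store.size());
        } else {
          ++n_h1_zero;
        }
      }
    }
  }

  // surviving components: infinite H0 bars
  for (int i = 0; i < n; ++i) {
    if (uf.find(i) == i) {
      int bv = birthv[i];
      bar_dim.push_back(0);
      bar_birth.push_back(0.0);
      bar_death.push_back(R_PosInf);
      bar_b1.push_back(bv + 1);
      bar_b2.push_back(NA_INTEGER);
      bar_b3.push_back(NA_INTEGER);
      bar_d1.push_back(NA_INTEGER);
      bar_d2.push_back(NA_INTEGER);
      bar_d3.push_back(NA_INTEGER);
      bar_cycle.push_back(NA_INTEGER);
    }
  }

  List cyc_out(cycle_store.size());
  for (size_t q = 0; q < cycle_store.size(); ++q) cyc_out[q] = cycle_store[q];

  DataFrame bars = DataFrame::create(
      _["dim"] = bar_dim, _["birth"] = bar_birth, _["death"] = bar_death,
      _["b1"] = bar_b1, _["b2"] = bar_b2, _["b3"] = bar_b3,
      _["d1"] = bar_d1, _["d2"] = bar_d2, _["d3"] = bar_d3,
      _["cycle_id"] = bar_cycle);

  return List::create(_["bars"] = bars, _["cycles"] = cyc_out,
                      _["n_points"] = n, _["max_scale"] = max_scale,
                      _["n_h0_zero"] = n_h0_zero,
                      _["n_h1_zero"] = n_h1_zero,
                      _["n_simplices"] = m);
}
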