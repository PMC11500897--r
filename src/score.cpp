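#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Genotype-combination counts for one SNP subset, split by class.
// g0/g1: control/case genotype matrices (values 0/1/2), idx: 0-based columns.
// Returns only combinations observed in at least one sample, keyed by
// sum_j g_j * 3^j (first selected SNP varies fastest).
static void combo_counts(const IntegerMatrix& g0, const IntegerMatrix& g1,
                         const IntegerVector& idx,
                         std::vector<int>& keys,
                         std::vector<double>& c0, std::vector<double>& c1) {
  const int k = idx.size();
  int nb = 1;
  for (int j = 0; j < k; ++j) nb *= 3;
  static std::vector<int> t0, t1, key0, key1;  // workspace; single-threaded use
  t0.assign(nb, 0); t1.assign(nb, 0);
  const int n0 = g0.nrow(), n1 = g1.nrow();
  key0.assign(n0, 0); key1.assign(n1, 0);
  int p3 = 1;
  for (int j = 0; j < k; ++j) {
    const int* c0p = g0.begin() + (R_xlen_t)idx[j] * n0;
    const int* c1p = g1.begin() + (R_xlen_t)idx[j] * n1;
    for (int i = 0; i < n0; ++i) key0[i] += c0p[i] * p3;
    for (int i = 0; i < n1; ++i) key1[i] += c1p[i] * p3;
    p3 *= 3;
  }
  for (int i = 0; i < n0; ++i) t0[key0[i]]++;
  for (int i = 0; i < n1; ++i) t1[key1[i]]++;
  keys.clear(); c0.clear(); c1.clear();
  for (int x = 0; x < nb; ++x)
    if (t0[x] + t1[x] > 0) {
      keys.push_back(x);
      c0.push_back(t0[x]);
      c1.push_back(t1[x]);
    }
}

// [[Rcpp::export]]
List combo_counts_cpp(const IntegerMatrix& g0, const IntegerMatrix& g1,
                      const IntegerVector& idx) {
  std::vector<int> keys;
  std::vector<double> c0, c1;
  combo_counts(g0, g1, idx, keys, c0, c1);
  return List::create(_["key"] = wrap(keys), _["n_control"] = wrap(c0),
                      _["n_case"] = wrap(c1));
}

// Competition rank sums over the three objective columns: for each member,
// sum over objectives of (1 + number of strictly smaller scores).
// [[Rcpp::export]]
IntegerVector rank_sums_cpp(const NumericMatrix& sc) {
  const int n = sc.nrow();
  IntegerVector out(n);
  std::vector<double> col(n);
  for (int j = 0; j < 3; ++j) {
    for (int i = 0; i < n; ++i) col[i] = sc(i, j);
    std::sort(col.begin(), col.end());
    for (int i = 0; i < n; ++i)
      out[i] += 1 + (int)(std::lower_bound(col.begin(), col.end(), sc(i, j)) -
                          col.begin());
  }
  return out;
}

// Permutation (1-based) sorting the population best-first by
// (rank sum, k2 score, insertion counter).
// [[Rcpp::export]]
IntegerVector pop_order_cpp(const NumericMatrix& sc,
                            const IntegerVector& ctr) {
  const int n = sc.nrow();
  IntegerVector rs = rank_sums_cpp(sc);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rs[a] != rs[b]) return rs[a] < rs[b];
    if (sc(a, 0) != sc(b, 0)) return sc(a, 0) < sc(b, 0);
    return ctr[a] < ctr[b];
  });
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ord[i] + 1;
  return out;
}

// Cell counts are integers, so log-gamma and log reduce to table lookups;
// the tables grow on demand and persist across calls (single-threaded use).
static std::vector<double> lgamma_tab, log_tab;
static inline void grow_tabs(int upto) {
  if ((int)lgamma_tab.size() <= upto) {
    size_t from = lgamma_tab.size();
    lgamma_tab.resize(upto + 1);
    log_tab.resize(upto + 1);
    for (size_t i = from; i <= (size_t)upto; ++i) {
      lgamma_tab[i] = lgamma((double)i);
      log_tab[i] = i > 0 ? std::log((double)i) : 0.0;
    }
  }
}

static inline double cell_k2(double a0, double a1) {
  // binary phenotype: ln((m_x+1)!) - ln(m_x0!) - ln(m_x1!)
  return lgamma_tab[(int)a0 + (int)a1 + 2] - lgamma_tab[(int)a0 + 1] -
         lgamma_tab[(int)a1 + 1];
}
static inline double cell_ce(double a0, double a1, double n) {
  const int m = (int)a0 + (int)a1;
  double e = 0.0;
  if (a0 > 0) e -= a0 * (log_tab[(int)a0] - log_tab[m]);
  if (a1 > 0) e -= a1 * (log_tab[(int)a1] - log_tab[m]);
  return e / n;
}
static inline double cell_gini(double a0, double a1, double n) {
  const double m = a0 + a1;
  const double q0 = a0 / m, q1 = a1 / m;
  return (m / n) * (1.0 - q0 * q0 - q1 * q1);
}

// K2 / CE / Gini with per-objective ml-truncation: when more than ml
// combinations are observed, the ml-1 cells with the LARGEST contribution to
// that objective (the weak-evidence cells) are kept individually and all
// remaining cells -- the many small, suspiciously pure cells that long
// tables accumulate by chance -- are pooled into one cell scored as an
// ordinary cell, so at most ml cells contribute. This removes the downward
// bias of all three objectives on long genotype tables. ml <= 0 disables
// truncation.
static void score_core(const IntegerMatrix& g0, const IntegerMatrix& g1,
                       const IntegerVector& idx, int ml, double out[3]) {
  std::vector<int> keys;
  std::vector<double> a0, a1;
  combo_counts(g0, g1, idx, keys, a0, a1);
  const int nc = (int)a0.size();
  const double n = g0.nrow() + g1.nrow();
  grow_tabs((int)n + 2);
  std::vector<double> contrib(nc);
  std::vector<int> ord(nc);
  for (int o = 0; o < 3; ++o) {
    for (int x = 0; x < nc; ++x)
      contrib[x] = (o == 0) ? cell_k2(a0[x], a1[x])
                 : (o == 1) ? cell_ce(a0[x], a1[x], n)
                            : cell_gini(a0[x], a1[x], n);
    double s = 0.0;
    if (ml <= 0 || nc <= ml) {
      for (int x = 0; x < nc; ++x) s += contrib[x];
    } else {
      for (int x = 0; x < nc; ++x) ord[x] = x;
      // only membership of the retained set matters (contributions are
      // summed), so a partial selection under the deterministic total order
      // (contribution desc, index asc) is exact
      std::nth_element(ord.begin(), ord.begin() + (ml - 1), ord.end(),
                       [&](int a, int b) {
        return contrib[a] > contrib[b] || (contrib[a] == contrib[b] && a < b);
      });
      double p0 = 0.0, p1 = 0.0;
      for (int r = 0; r < ml - 1; ++r) s += contrib[ord[r]];
      for (int r = ml - 1; r < nc; ++r) { p0 += a0[ord[r]]; p1 += a1[ord[r]]; }
      s += (o == 0) ? cell_k2(p0, p1)
         : (o == 1) ? cell_ce(p0, p1, n)
                    : cell_gini(p0, p1, n);
    }
    out[o] = s;
  }
}

// [[Rcpp::export]]
NumericVector score_combo_cpp(const IntegerMatrix& g0, const IntegerMatrix& g1,
                              const IntegerVector& idx, int ml) {
  double v[3];
  score_core(g0, g1, idx, ml, v);
  NumericVector out = NumericVector::create(v[0], v[1], v[2]);
  out.names() = CharacterVector::create("k2", "ce", "gini");
  return out;
}

// ---------------------------------------------------------------------------
// Population engine: a memoised score cache plus the sparrow population,
// kept sorted best-first by (rank sum, k2, insertion counter) with ranks
// recomputed in full after every insertion or removal. All randomness stays
// on the R side; this object only stores, scores, ranks and sorts.

struct SparrowEngine {
  IntegerMatrix g0, g1;   // class-split genotype matrices (shared with R)
  int ml, mo, N;
  std::unordered_map<std::string, std::array<double, 3>> memo;
  std::unordered_map<std::string, double> memo_raw;  // untruncated K2
  std::vector<std::vector<int>> pos;   // 1-based SNP indices, length mo
  std::vector<std::array<double, 3>> sc;
  std::vector<int> ctr;
  int next_ctr = 1;

  SparrowEngine(IntegerMatrix g0_, IntegerMatrix g1_, int ml_, int mo_)
    : g0(g0_), g1(g1_), ml(ml_), mo(mo_), N(g0_.ncol()) {}

  int size() const { return (int)pos.size(); }

  const std::array<double, 3>& score(const std::vector<int>& idx1) {
    std::vector<int> s(idx1);
    std::sort(s.begin(), s.end());
    std::string key(reinterpret_cast<const char*>(s.data()),
                    s.size() * sizeof(int));
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    IntegerVector idx0(s.size());
    for (size_t j = 0; j < s.size(); ++j) idx0[j] = s[j] - 1;
    std::array<double, 3> v;
    score_core(g0, g1, idx0, ml, v.data());
    return memo.emplace(key, v).first->second;
  }

  // Raw (untruncated) K2, the score backward noise elimination descends on.
  double raw_k2(const std::vector<int>& idx1) {
    std::vector<int> s(idx1);
    std::sort(s.begin(), s.end());
    std::string key(reinterpret_cast<const char*>(s.data()),
                    s.size() * sizeof(int));
    auto it = memo_raw.find(key);
    if (it != memo_raw.end()) return it->second;
    IntegerVector idx0(s.size());
    for (size_t j = 0; j < s.size(); ++j) idx0[j] = s[j] - 1;
    double v[3];
    score_core(g0, g1, idx0, 0, v);
    memo_raw.emplace(key, v[0]);
    return v[0];
  }

  std::vector<int> rank_sums() const {
    const int n = size();
    std::vector<int> rs(n, 0);
    std::vector<double> col(n);
    for (int o = 0; o < 3; ++o) {
      for (int i = 0; i < n; ++i) col[i] = sc[i][o];
      std::sort(col.begin(), col.end());
      for (int i = 0; i < n; ++i)
        rs[i] += 1 + (int)(std::lower_bound(col.begin(), col.end(),
                                            sc[i][o]) - col.begin());
    }
    return rs;
  }

  void resort() {
    const int n = size();
    std::vector<int> rs = rank_sums();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (rs[a] != rs[b]) return rs[a] < rs[b];
      if (sc[a][0] != sc[b][0]) return sc[a][0] < sc[b][0];
      return ctr[a] < ctr[b];
    });
    apply_perm(ord);
  }

  void apply_perm(const std::vector<int>& ord) {
    std::vector<std::vector<int>> pos2(ord.size());
    std::vector<std::array<double, 3>> sc2(ord.size());
    std::vector<int> ctr2(ord.size());
    for (size_t i = 0; i < ord.size(); ++i) {
      pos2[i] = pos[ord[i]]; sc2[i] = sc[ord[i]]; ctr2[i] = ctr[ord[i]];
    }
    pos.swap(pos2); sc.swap(sc2); ctr.swap(ctr2);
  }

  void add(const std::vector<int>& x) {
    pos.push_back(x);
    sc.push_back(score(x));
    ctr.push_back(next_ctr++);
    resort();
  }

  void drop(int i) {  // 0-based
    pos.erase(pos.begin() + i);
    sc.erase(sc.begin() + i);
    ctr.erase(ctr.begin() + i);
  }

  // Insert a proposal, keep the better of {incumbent at 0-based row i,
  // proposal} under recomputed ranks (ties keep the incumbent), re-sort.
  void keep_better(int i, const std::vector<int>& x) {
    pos.push_back(x);
    sc.push_back(score(x));
    ctr.push_back(next_ctr++);
    std::vector<int> rs = rank_sums();
    const int m = size() - 1;
    drop(rs[m] < rs[i] ? i : m);
    resort();
  }
};

typedef Rcpp::XPtr<SparrowEngine> EngPtr;

static std::vector<int> as_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export]]
SEXP eng_new(IntegerMatrix g0, IntegerMatrix g1, int ml, int mo) {
  return EngPtr(new SparrowEngine(g0, g1, ml, mo), true);
}

// [[Rcpp::export]]
void eng_init_pop(SEXP p, IntegerMatrix positions) {
  EngPtr e(p);
  e->pos.clear(); e->sc.clear(); e->ctr.clear();
  e->next_ctr = 1;
  for (int i = 0; i < positions.nrow(); ++i) {
    std::vector<int> row(positions.ncol());
    for (int j = 0; j < positions.ncol(); ++j) row[j] = positions(i, j);
    e->pos.push_back(row);
    e->sc.push_back(e->score(row));
    e->ctr.push_back(e->next_ctr++);
  }
  e->resort();
}

// [[Rcpp::export]]
int eng_size(SEXP p) { return EngPtr(p)->size(); }

// [[Rcpp::export]]
IntegerMatrix eng_positions(SEXP p) {
  EngPtr e(p);
  IntegerMatrix out(e->size(), e->mo);
  for (int i = 0; i < e->size(); ++i)
    for (int j = 0; j < e->mo; ++j) out(i, j) = e->pos[i][j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix eng_scores(SEXP p) {
  EngPtr e(p);
  NumericMatrix out(e->size(), 3);
  for (int i = 0; i < e->size(); ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = e->sc[i][j];
  return out;
}

// [[Rcpp::export]]
IntegerVector eng_counters(SEXP p) { return wrap(EngPtr(p)->ctr); }

// [[Rcpp::export]]
IntegerVector eng_rank_sums(SEXP p) { return wrap(EngPtr(p)->rank_sums()); }

// [[Rcpp::export]]
IntegerVector eng_row(SEXP p, int i) { return wrap(EngPtr(p)->pos[i - 1]); }

// [[Rcpp::export]]
void eng_keep_better(SEXP p, int i, IntegerVector x) {
  EngPtr(p)->keep_better(i - 1, as_vec(x));
}

// [[Rcpp::export]]
void eng_add(SEXP p, IntegerVector x) { EngPtr(p)->add(as_vec(x)); }

// Remove `count` members from the top (local optimum) or bottom, then
// re-sort under recomputed ranks.
// [[Rcpp::export]]
void eng_trim(SEXP p, bool local_optimum, int count) {
  EngPtr e(p);
  if (local_optimum) {
    e->pos.erase(e->pos.begin(), e->pos.begin() + count);
    e->sc.erase(e->sc.begin(), e->sc.begin() + count);
    e->ctr.erase(e->ctr.begin(), e->ctr.begin() + count);
  } else {
    e->pos.resize(e->size() - count);
    e->sc.resize(e->sc.size() - count);
    e->ctr.resize(e->ctr.size() - count);
  }
  e->resort();
}

// Memoised (k2, ce, gini) for an arbitrary SNP index set (1-based).
// [[Rcpp::export]]
NumericVector eng_score_set(SEXP p, IntegerVector idx) {
  const std::array<double, 3>& v = EngPtr(p)->score(as_vec(idx));
  return NumericVector::create(v[0], v[1], v[2]);
}

// Memoised untruncated K2 (1-based indices).
// [[Rcpp::export]]
double eng_raw_k2(SEXP p, IntegerVector idx) {
  return EngPtr(p)->raw_k2(as_vec(idx));
}

// Number of distinct SNP indices across all position vectors.
// [[Rcpp::export]]
int eng_distinct(SEXP p) {
  EngPtr e(p);
  std::unordered_set<int> seen;
  for (const auto& row : e->pos) seen.insert(row.begin(), row.end());
  return (int)seen.size();
}
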