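// Random survival forest core: bootstrap survival trees with log-rank
// splitting, unique-death stopping and Nelson-Aalen leaf cumulative hazards.
// Features are integer-coded categoricals; ordered features split by
// threshold, unordered by one-level-vs-rest.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// Deterministic 64-bit RNG (xorshift*); avoids implementation-defined
// std::uniform_int_distribution so fits reproduce across platforms.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {
    if (s == 0) s = 88172645463325252ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct NodeRec {
  int var, split_type, split_val, left, right, leaf_id, n_left, n_right;
};

// Two-sample log-rank scan over node rows sorted by increasing day.
// `grp` marks membership of the left daughter. Returns the standardized
// |O - E| / sqrt(V) statistic (0 when V == 0) and counts the distinct event
// times within each daughter.
double logrank_scan(const std::vector<double>& day, const std::vector<int>& ev,
                    const std::vector<char>& grp,
                    int* uniq_left, int* uniq_right) {
  const int n = (int)day.size();
  int y = n;
  int y1 = 0;
  for (int i = 0; i < n; ++i) if (grp[i]) ++y1;
  double ome = 0.0, v = 0.0;
  int ul = 0, ur = 0;
  int i = 0;
  while (i < n) {
    double t = day[i];
    int d = 0, d1 = 0;
    int j = i;
    while (j < n && day[j] == t) {
      if (ev[j]) { ++d; if (grp[j]) ++d1; }
      ++j;
    }
    if (d > 0) {
      double p1 = (double)y1 / (double)y;
      ome += d1 - d * p1;
      if (y > 1) v += d * p1 * (1.0 - p1) * (double)(y - d) / (double)(y - 1);
      if (d1 > 0) ++ul;
      if (d1 < d) ++ur;
    }
    // remove processed rows from the risk set
    while (i < j) {
      --y;
      if (grp[i]) --y1;
      ++i;
    }
  }
  if (uniq_left) *uniq_left = ul;
  if (uniq_right) *uniq_right = ur;
  if (v <= 0.0) return 0.0;
  return std::fabs(ome) / std::sqrt(v);
}

struct TreeBuilder {
  const IntegerMatrix& X;
  const IntegerVector& n_levels;
  const LogicalVector& ordered;
  const NumericVector& day;
  const IntegerVector& status;
  int n_candidates, min_ud;
  Rng& rng;
  std::vector<NodeRec> nodes;
  std::vector<std::vector<double> > leaf_chf;  // per leaf, on grid
  const std::vector<double>& grid;

  TreeBuilder(const IntegerMatrix& X_, const IntegerVector& nl,
              const LogicalVector& ord, const NumericVector& d,
              const IntegerVector& st, int ncand, int mud, Rng& r,
              const std::vector<double>& g)
    : X(X_), n_levels(nl), ordered(ord), day(d), status(st),
      n_candidates(ncand), min_ud(mud), rng(r), grid(g) {}

  // Nelson-Aalen CHF of `rows` (bootstrap multiplicity = repeats) evaluated
  // on the global event-time grid.
  std::vector<double> nelson_aalen_on_grid(const std::vector<int>& rows) {
    std::vector<int> idx(rows);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return day[a] < day[b]; });
    const int n = (int)idx.size();
    std::vector<double> chf(grid.size(), 0.0);
    double acc = 0.0;
    size_t g = 0;
    int i = 0, y = n;
    while (i < n) {
      double t = day[idx[i]];
      int d = 0;
      int j = i;
      while (j < n && day[idx[j]] == t) { if (status[idx[j]]) ++d; ++j; }
      if (d > 0) {
        while (g < grid.size() && grid[g] < t) { chf[g] = acc; ++g; }
        acc += (double)d / (double)y;
      }
      y -= (j - i);
      i = j;
    }
    for (; g < grid.size(); ++g) chf[g] = acc;
    return chf;
  }

  int make_leaf(const std::vector<int>& rows) {
    NodeRec nd;
    nd.var = -1; nd.split_type = 0; nd.split_val = 0;
    nd.left = -1; nd.right = -1;
    nd.leaf_id = (int)leaf_chf.size();
    nd.n_left = 0; nd.n_right = (int)rows.size();
    leaf_chf.push_back(nelson_aalen_on_grid(rows));
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int grow(const std::vector<int>& rows) {
    const int n = (int)rows.size();
    // sort rows by day once; log-rank scans reuse this order
    std::vector<int> srt(rows);
    std::sort(srt.begin(), srt.end(), [&](int a, int b) { return day[a] < day[b]; });
    std::vector<double> sday(n);
    std::vector<int> sev(n);
    for (int i = 0; i < n; ++i) { sday[i] = day[srt[i]]; sev[i] = status[srt[i]]; }

    // quick stop: fewer than 2*D unique death times cannot split admissibly
    int uniq_deaths = 0;
    {
      double last = -1.0;
      for (int i = 0; i < n; ++i) {
        if (sev[i] && sday[i] != last) { ++uniq_deaths; last = sday[i]; }
      }
    }
    int best_var = -1, best_type = 0, best_val = 0;
    double best_score = -1.0;
    if (uniq_deaths >= 2 * min_ud && n >= 2) {
      const int p = X.ncol();
      int ncand = std::min(n_candidates, p);
      // partial Fisher-Yates over covariate indices
      std::vector<int> cand(p);
      for (int j = 0; j < p; ++j) cand[j] = j;
      for (int j = 0; j < ncand; ++j) {
        int k = j + rng.below(p - j);
        std::swap(cand[j], cand[k]);
      }
      std::vector<char> grp(n);
      for (int c = 0; c < ncand; ++c) {
        int var = cand[c];
        int L = n_levels[var];
        int nsplits = ordered[var] ? (L - 1) : L;
        for (int s = 0; s < nsplits; ++s) {
          int n_left = 0;
          if (ordered[var]) {
            for (int i = 0; i < n; ++i) {
              grp[i] = X(srt[i], var) <= s;
              if (grp[i]) ++n_left;
            }
          } else {
            for (int i = 0; i < n; ++i) {
              grp[i] = X(srt[i], var) == s;
              if (grp[i]) ++n_left;
            }
          }
          if (n_left == 0 || n_left == n) continue;
          int ul = 0, ur = 0;
          double sc = logrank_scan(sday, sev, grp, &ul, &ur);
          if (ul < min_ud || ur < min_ud) continue;
          if (sc > best_score) {
            best_score = sc; best_var = var; best_type = ordered[var] ? 0 : 1;
            best_val = s;
          }
        }
      }
    }
    if (best_var < 0) return make_leaf(rows);

    std::vector<int> lrows, rrows;
    for (int i = 0; i < n; ++i) {
      int v = X(rows[i], best_var);
      bool left = (best_type == 0) ? (v <= best_val) : (v == best_val);
      if (left) lrows.push_back(rows[i]); else rrows.push_back(rows[i]);
    }
    NodeRec nd;
    nd.var = best_var; nd.split_type = best_type; nd.split_val = best_val;
    nd.leaf_id = -1;
    nd.n_left = (int)lrows.size(); nd.n_right = (int)rrows.size();
    nd.left = -1; nd.right = -1;
    nodes.push_back(nd);
    int self = (int)nodes.size() - 1;
    int li = grow(lrows);
    int ri = grow(rrows);
    nodes[self].left = li;
    nodes[self].right = ri;
    return self;
  }
};

int route_to_leaf(const IntegerMatrix& nodes, const IntegerMatrix& Xnew,
                  int row, const IntegerVector& n_levels) {
  int cur = 0;
  while (nodes(cur, 0) >= 0) {
    int var = nodes(cur, 0);
    int type = nodes(cur, 1);
    int val = nodes(cur, 2);
    int v = Xnew(row, var);
    bool left;
    if (v < 0 || v >= n_levels[var] || v == NA_INTEGER) {
      left = nodes(cur, 6) >= nodes(cur, 7);  // majority daughter
    } else {
      left = (type == 0) ? (v <= val) : (v == val);
    }
    cur = left ? nodes(cur, 3) : nodes(cur, 4);
  }
  return nodes(cur, 5);
}

}  // namespace

// [[Rcpp::export]]
double logrank_score_cpp(NumericVector day, IntegerVector status,
                         IntegerVector group) {
  const int n = day.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return day[a] < day[b]; });
  std::vector<double> sday(n);
  std::vector<int> sev(n);
  std::vector<char> grp(n);
  for (int i = 0; i < n; ++i) {
    sday[i] = day[idx[i]];
    sev[i] = status[idx[i]];
    grp[i] = group[idx[i]] != 0;
  }
  return logrank_scan(sday, sev, grp, nullptr, nullptr);
}

// [[Rcpp::export]]
List rsf_fit_cpp(IntegerMatrix X, IntegerVector n_levels, LogicalVector ordered,
                 NumericVector day, IntegerVector status, int n_trees,
                 int n_candidates, int min_unique_deaths, double seed,
                 NumericVector grid_times) {
  const int n = X.nrow();
  std::vector<double> grid(grid_times.begin(), grid_times.end());
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees);
  for (int t = 0; t < n_trees; ++t) {
    Rng rng((uint64_t)seed * 1000003ULL + (uint64_t)t + 1ULL);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int k = rng.below(n);
      rows[i] = k;
      inbag(k, t) += 1;
    }
    TreeBuilder tb(X, n_levels, ordered, day, status, n_candidates,
                   min_unique_deaths, rng, grid);
    tb.grow(rows);
    int nn = (int)tb.nodes.size();
    IntegerMatrix nm(nn, 8);
    for (int i = 0; i < nn; ++i) {
      const NodeRec& r = tb.nodes[i];
      nm(i, 0) = r.var; nm(i, 1) = r.split_type; nm(i, 2) = r.split_val;
      nm(i, 3) = r.left; nm(i, 4) = r.right; nm(i, 5) = r.leaf_id;
      nm(i, 6) = r.n_left; nm(i, 7) = r.n_right;
    }
    int nl = (int)tb.leaf_chf.size();
    NumericMatrix lc(nl, (int)grid.size());
    for (int i = 0; i < nl; ++i) {
      for (size_t g = 0; g < grid.size(); ++g) lc(i, (int)g) = tb.leaf_chf[i][g];
    }
    trees[t] = List::create(Named("nodes") = nm, Named("leaf_chf") = lc);
  }
  return List::create(Named("trees") = trees, Named("inbag") = inbag,
                      Named("grid") = grid_times);
}

// [[Rcpp::export]]
List rsf_predict_cpp(List forest, IntegerMatrix Xnew, IntegerVector n_levels,
                     Nullable<IntegerMatrix> use_tree) {
  List trees = forest["trees"];
  NumericVector grid = forest["grid"];
  const int n_trees = trees.size();
  const int n = Xnew.nrow();
  const int ng = grid.size();
  NumericMatrix chf(n, ng);
  IntegerVector used(n);
  bool masked = use_tree.isNotNull();
  IntegerMatrix mask;
  if (masked) mask = use_tree.get();
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerMatrix nodes = tr["nodes"];
    NumericMatrix lc = tr["leaf_chf"];
    for (int i = 0; i < n; ++i) {
      if (masked && mask(i, t) == 0) continue;
      int leaf = route_to_leaf(nodes, Xnew, i, n_levels);
      for (int g = 0; g < ng; ++g) chf(i, g) += lc(leaf, g);
      used[i] += 1;
    }
  }
  for (int i = 0; i < n; ++i) {
    if (used[i] > 0) {
      for (int g = 0; g < ng; ++g) chf(i, g) /= used[i];
    } else {
      for (int g = 0; g < ng; ++g) chf(i, g) = NA_REAL;
    }
  }
  return List::create(Named("chf") = chf, Named("n_trees_used") = used);
}
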