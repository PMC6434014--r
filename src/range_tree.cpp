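// Static range-tree kernels shared by the fractional-cascading tree (RTFC)
// and the basic 2-D range tree (2D-RT).
//
// Layout: nodes are stored structure-of-arrays, 1-based ids, 0 = no child.
// Intervals are handled by x-rank: the caller passes coordinates already
// sorted by (start, index); rank r (1-based) identifies the r-th interval
// in that order. Each node's y-sorted data array (ranks ordered by
// (end, index)) lives in a shared pool at [off, off+len). FC-index entries
// are 0-based positions into the corresponding child's data array, with -1
// meaning "no element in the child is >= this one".
//
// All query bounds arrive as effective *closed* bounds (open integer bounds
// are normalized to closed ones by the R layer); +-Inf encode unbounded
// sides.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Builder {
  const NumericVector& xs;  // x-rank order
  const NumericVector& ys;
  const IntegerVector& ids;
  bool with_fc;
  std::vector<double> key;
  std::vector<int> left, right, leafrank, off, len;
  std::vector<int> pool_rank, pool_lfc, pool_rfc;  // pool_rank 0-based here

  Builder(const NumericVector& x, const NumericVector& y,
          const IntegerVector& id, bool fc)
      : xs(x), ys(y), ids(id), with_fc(fc) {}

  bool yless(int a, int b) const {  // order by (end, provenance index)
    if (ys[a] != ys[b]) return ys[a] < ys[b];
    return ids[a] < ids[b];
  }

  int new_node() {
    key.push_back(0.0);
    left.push_back(0);
    right.push_back(0);
    leafrank.push_back(0);
    off.push_back(0);
    len.push_back(0);
    return static_cast<int>(key.size());  // 1-based id
  }

  void store(int v, const std::vector<int>& data, const std::vector<int>& lfc,
             const std::vector<int>& rfc) {
    off[v - 1] = static_cast<int>(pool_rank.size()) + 1;
    len[v - 1] = static_cast<int>(data.size());
    pool_rank.insert(pool_rank.end(), data.begin(), data.end());
    if (with_fc) {
      pool_lfc.insert(pool_lfc.end(), lfc.begin(), lfc.end());
      pool_rfc.insert(pool_rfc.end(), rfc.begin(), rfc.end());
    }
  }

  // build over 0-based rank range [lo, hi]; out receives the y-sorted ranks
  int build(int lo, int hi, std::vector<int>& out) {
    int v = new_node();
    if (lo == hi) {
      key[v - 1] = xs[lo];
      leafrank[v - 1] = lo + 1;
      out.assign(1, lo);
      std::vector<int> none(1, -1);
      store(v, out, none, none);
      return v;
    }
    // split at the median x-value: everything <= x_mid goes left; if that
    // would leave the right side empty (all x equal), fall back to a rank
    // split so both halves stay non-empty and the tree stays balanced
    int s = hi - lo + 1;
    int midrank = lo + (s + 1) / 2 - 1;  // ceil(s/2)-th smallest, 0-based
    double xmid = xs[midrank];
    const double* base = &xs[0];
    int cut = static_cast<int>(std::upper_bound(base + lo, base + hi + 1, xmid) -
                               base) - 1;
    if (cut >= hi) cut = midrank;
    std::vector<int> dl, dr;
    int vl = build(lo, cut, dl);
    int vr = build(cut + 1, hi, dr);
    key[v - 1] = xs[cut];  // largest x in the left subtree
    left[v - 1] = vl;
    right[v - 1] = vr;
    // y-sorted merge of the children's data arrays
    std::vector<int> merged;
    merged.reserve(dl.size() + dr.size());
    size_t i = 0, j = 0;
    while (i < dl.size() && j < dr.size())
      merged.push_back(yless(dl[i], dr[j]) ? dl[i++] : dr[j++]);
    while (i < dl.size()) merged.push_back(dl[i++]);
    while (j < dr.size()) merged.push_back(dr[j++]);
    std::vector<int> lfc, rfc;
    if (with_fc) {
      lfc.resize(merged.size());
      rfc.resize(merged.size());
      size_t pl = 0, pr = 0;
      for (size_t t = 0; t < merged.size(); ++t) {
        double yv = ys[merged[t]];
        while (pl < dl.size() && ys[dl[pl]] < yv) ++pl;
        lfc[t] = pl < dl.size() ? static_cast<int>(pl) : -1;
        while (pr < dr.size() && ys[dr[pr]] < yv) ++pr;
        rfc[t] = pr < dr.size() ? static_cast<int>(pr) : -1;
      }
    }
    store(v, merged, lfc, rfc);
    out = std::move(merged);
    return v;
  }
};

// read-only view over a tree list coming back from R
struct Tree {
  int root;
  IntegerVector left, right, leaf, off, len, pool_rank, pool_lfc, pool_rfc, id;
  NumericVector key, x, y;
  bool with_fc;

  explicit Tree(const List& t)
      : root(as<int>(t["root"])),
        left(t["left"]), right(t["right"]), leaf(t["leaf"]), off(t["off"]),
        len(t["len"]), pool_rank(t["pool_rank"]),
        pool_lfc(t.containsElementNamed("pool_lfc") ? t["pool_lfc"]
                                                    : IntegerVector(0)),
        pool_rfc(t.containsElementNamed("pool_rfc") ? t["pool_rfc"]
                                                    : IntegerVector(0)),
        id(t["id"]), key(t["key"]), x(t["x"]), y(t["y"]) {
    with_fc = pool_lfc.size() > 0;
  }

  bool is_leaf(int v) const { return leaf[v - 1] > 0; }
  int rank_at(int v, int pos) const { return pool_rank[off[v - 1] - 1 + pos]; }
  double y_at(int v, int pos) const { return y[rank_at(v, pos) - 1]; }
  int id_at(int v, int pos) const { return id[rank_at(v, pos) - 1]; }
  int lfc_at(int v, int pos) const { return pool_lfc[off[v - 1] - 1 + pos]; }
  int rfc_at(int v, int pos) const { return pool_rfc[off[v - 1] - 1 + pos]; }
  // first position in v's data with y >= t, or len if none
  int lower_pos(int v, double t, int* steps = nullptr) const {
    int lo = 0, hi = len[v - 1];
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (steps) ++*steps;
      if (y_at(v, mid) < t) lo = mid + 1; else hi = mid;
    }
    return lo;
  }
};

// descend from the root until the search paths for x1 and x2 diverge
// (x1 <= key <= x2) or a leaf is reached; counts nodes touched
int find_split(const Tree& T, double x1, double x2, int& visits) {
  int v = T.root;
  while (true) {
    ++visits;
    if (T.is_leaf(v)) return v;
    double k = T.key[v - 1];
    if (x2 < k) v = T.left[v - 1];
    else if (x1 > k) v = T.right[v - 1];
    else return v;
  }
}

void leaf_check(const Tree& T, int v, double x1, double x2, double y1,
                double y2, std::vector<int>& res) {
  int r = T.leaf[v - 1];
  double xv = T.x[r - 1], yv = T.y[r - 1];
  if (xv >= x1 && xv <= x2 && yv >= y1 && yv <= y2) res.push_back(T.id[r - 1]);
}

// report a child's data run starting at 0-based position j0 (-1 = nothing)
void report_run(const Tree& T, int child, int j0, double y2,
                std::vector<int>& res, int& reported) {
  if (j0 < 0) return;
  int n = T.len[child - 1];
  for (int j = j0; j < n; ++j) {
    if (T.y_at(child, j) > y2) break;
    res.push_back(T.id_at(child, j));
    ++reported;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericVector xs, NumericVector ys, IntegerVector ids,
                    bool with_fc) {
  if (xs.size() == 0) stop("empty interval set");
  Builder b(xs, ys, ids, with_fc);
  std::vector<int> root_data;
  int root = b.build(0, static_cast<int>(xs.size()) - 1, root_data);
  // pool ranks go out 1-based
  IntegerVector pr(b.pool_rank.size());
  for (size_t i = 0; i < b.pool_rank.size(); ++i) pr[i] = b.pool_rank[i] + 1;
  List out = List::create(
      _["root"] = root, _["key"] = wrap(b.key), _["left"] = wrap(b.left),
      _["right"] = wrap(b.right), _["leaf"] = wrap(b.leafrank),
      _["off"] = wrap(b.off), _["len"] = wrap(b.len), _["pool_rank"] = pr);
  if (with_fc) {
    out["pool_lfc"] = wrap(b.pool_lfc);
    out["pool_rfc"] = wrap(b.pool_rfc);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_find_split(List tree, double x1, double x2) {
  Tree T(tree);
  int visits = 0;
  int v = find_split(T, x1, x2, visits);
  return List::create(_["node"] = v, _["visits"] = visits);
}

// Fractional-cascading query: one binary search for y1 at the split node,
// then constant-time index propagation along both descent paths.
// [[Rcpp::export]]
List cpp_query_rtfc(List tree, double x1, double x2, double y1, double y2) {
  Tree T(tree);
  std::vector<int> res;
  int visits = 0, reported = 0;
  if (x1 > x2 || y1 > y2)
    return List::create(_["ids"] = wrap(res), _["visits"] = visits,
                        _["reported"] = reported);
  int vs = find_split(T, x1, x2, visits);
  if (T.is_leaf(vs)) {
    leaf_check(T, vs, x1, x2, y1, y2, res);
    reported = static_cast<int>(res.size());
    return List::create(_["ids"] = wrap(res), _["visits"] = visits,
                        _["reported"] = reported);
  }
  int i0 = T.lower_pos(vs, y1);
  if (i0 < T.len[vs - 1]) {
    // left walk: right children between the paths are fully inside [x1,x2]
    int v = T.left[vs - 1];
    int i = T.lfc_at(vs, i0);
    while (i != -1) {
      ++visits;
      if (T.is_leaf(v)) {
        leaf_check(T, v, x1, x2, y1, y2, res);
        break;
      }
      if (x1 <= T.key[v - 1]) {
        ++visits;  // the reported right child is touched
        report_run(T, T.right[v - 1], T.rfc_at(v, i), y2, res, reported);
        i = T.lfc_at(v, i);
        v = T.left[v - 1];
      } else {
        i = T.rfc_at(v, i);
        v = T.right[v - 1];
      }
    }
    // right walk, mirrored
    v = T.right[vs - 1];
    i = T.rfc_at(vs, i0);
    while (i != -1) {
      ++visits;
      if (T.is_leaf(v)) {
        leaf_check(T, v, x1, x2, y1, y2, res);
        break;
      }
      if (x2 >= T.key[v - 1]) {
        ++visits;
        report_run(T, T.left[v - 1], T.lfc_at(v, i), y2, res, reported);
        i = T.rfc_at(v, i);
        v = T.right[v - 1];
      } else {
        i = T.lfc_at(v, i);
        v = T.left[v - 1];
      }
    }
  }
  std::sort(res.begin(), res.end());
  return List::create(_["ids"] = wrap(res), _["visits"] = visits,
                      _["reported"] = static_cast<int>(res.size()));
}

// Basic 2-D range tree query: canonical-subtree decomposition on x, then an
// independent binary search for y1 in each canonical node's y-array. Each
// binary-search halving step counts as one visit (a node of the flattened
// 1-D y-tree), which is what makes the O(log^2 n) behaviour observable.
// [[Rcpp::export]]
List cpp_query_rt2d(List tree, double x1, double x2, double y1, double y2) {
  Tree T(tree);
  std::vector<int> res;
  int visits = 0;
  if (x1 > x2 || y1 > y2)
    return List::create(_["ids"] = wrap(res), _["visits"] = visits,
                        _["reported"] = 0);
  int vs = find_split(T, x1, x2, visits);
  int reported = 0;
  auto canonical = [&](int c) {
    ++visits;  // the canonical node itself
    int steps = 0;
    int j0 = T.lower_pos(c, y1, &steps);
    visits += steps;
    if (j0 < T.len[c - 1]) report_run(T, c, j0, y2, res, reported);
  };
  if (T.is_leaf(vs)) {
    leaf_check(T, vs, x1, x2, y1, y2, res);
  } else {
    int v = T.left[vs - 1];
    while (true) {
      ++visits;
      if (T.is_leaf(v)) {
        leaf_check(T, v, x1, x2, y1, y2, res);
        break;
      }
      if (x1 <= T.key[v - 1]) {
        canonical(T.right[v - 1]);
        v = T.left[v - 1];
      } else {
        v = T.right[v - 1];
      }
    }
    v = T.right[vs - 1];
    while (true) {
      ++visits;
      if (T.is_leaf(v)) {
        leaf_check(T, v, x1, x2, y1, y2, res);
        break;
      }
      if (x2 >= T.key[v - 1]) {
        canonical(T.left[v - 1]);
        v = T.right[v - 1];
      } else {
        v = T.left[v - 1];
      }
    }
  }
  std::sort(res.begin(), res.end());
  return List::create(_["ids"] = wrap(res), _["visits"] = visits,
                      _["reported"] = static_cast<int>(res.size()));
}

// Audit: at every internal node the cascaded child position must equal an
// independent binary search in the child's array. Returns mismatch count.
// [[Rcpp::export]]
int cpp_fc_audit(List tree, NumericVector probes) {
  Tree T(tree);
  if (!T.with_fc) stop("tree has no FC indices");
  int bad = 0;
  int nn = static_cast<int>(T.key.size());
  for (int v = 1; v <= nn; ++v) {
    if (T.is_leaf(v)) continue;
    int lc = T.left[v - 1], rc = T.right[v - 1];
    for (R_xlen_t p = 0; p < probes.size(); ++p) {
      double t = probes[p];
      int i = T.lower_pos(v, t);
      int want_l = T.lower_pos(lc, t);
      int want_r = T.lower_pos(rc, t);
      int got_l = i < T.len[v - 1] ? T.lfc_at(v, i) : -1;
      int got_r = i < T.len[v - 1] ? T.rfc_at(v, i) : -1;
      if (want_l == T.len[lc - 1]) want_l = -1;
      if (want_r == T.len[rc - 1]) want_r = -1;
      if (got_l != want_l) ++bad;
      if (got_r != want_r) ++bad;
    }
  }
  return bad;
}

// Audit: every internal node's data array is the exact y-sorted merge of
// its children's arrays; returns the number of offending nodes.
// [[Rcpp::export]]
int cpp_check_merge(List tree) {
  Tree T(tree);
  int bad = 0;
  int nn = static_cast<int>(T.key.size());
  for (int v = 1; v <= nn; ++v) {
    if (T.is_leaf(v)) continue;
    int lc = T.left[v - 1], rc = T.right[v - 1];
    std::vector<int> kids;
    for (int j = 0; j < T.len[lc - 1]; ++j) kids.push_back(T.rank_at(lc, j));
    for (int j = 0; j < T.len[rc - 1]; ++j) kids.push_back(T.rank_at(rc, j));
    auto lt = [&](int a, int b) {
      if (T.y[a - 1] != T.y[b - 1]) return T.y[a - 1] < T.y[b - 1];
      return T.id[a - 1] < T.id[b - 1];
    };
    std::sort(kids.begin(), kids.end(), lt);
    bool ok = static_cast<int>(kids.size()) == T.len[v - 1];
    if (ok) {
      for (int j = 0; j < T.len[v - 1]; ++j) {
        if (kids[j] != T.rank_at(v, j)) { ok = false; break; }
      }
      // and the parent itself must be y-sorted
      for (int j = 1; ok && j < T.len[v - 1]; ++j) {
        if (lt(T.rank_at(v, j), T.rank_at(v, j - 1))) ok = false;
      }
    }
    if (!ok) ++bad;
  }
  return bad;
}
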