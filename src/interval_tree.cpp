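// Augmented red-black interval tree: nodes keyed on interval start (ties
// broken by end, then provenance index), each augmented with the maximum
// end value in its subtree so that overlap queries can prune whole
// subtrees. Built by iterative insertion with the standard red-black
// insert/fixup, the augmentation maintained through rotations.
//
// Nodes are stored structure-of-arrays with 1-based ids; 0 is the nil
// sentinel. "inspected" counts the nodes whose interval is examined during
// a query, which is the quantity that scales with m (the number of
// overlap candidates) rather than k (the refined result size).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct IT {
  std::vector<double> start_, end_, maxend;
  std::vector<int> id, left, right, parent;
  std::vector<char> red;
  int root = 0;

  int size() const { return static_cast<int>(start_.size()); }

  bool less(double s, double e, int i, int v) const {
    if (s != start_[v - 1]) return s < start_[v - 1];
    if (e != end_[v - 1]) return e < end_[v - 1];
    return i < id[v - 1];
  }

  void update_maxend(int v) {
    double m = end_[v - 1];
    if (left[v - 1]) m = std::max(m, maxend[left[v - 1] - 1]);
    if (right[v - 1]) m = std::max(m, maxend[right[v - 1] - 1]);
    maxend[v - 1] = m;
  }

  void rotate_left(int x) {
    int y = right[x - 1];
    right[x - 1] = left[y - 1];
    if (left[y - 1]) parent[left[y - 1] - 1] = x;
    parent[y - 1] = parent[x - 1];
    if (!parent[x - 1]) root = y;
    else if (left[parent[x - 1] - 1] == x) left[parent[x - 1] - 1] = y;
    else right[parent[x - 1] - 1] = y;
    left[y - 1] = x;
    parent[x - 1] = y;
    update_maxend(x);
    update_maxend(y);
  }

  void rotate_right(int x) {
    int y = left[x - 1];
    left[x - 1] = right[y - 1];
    if (right[y - 1]) parent[right[y - 1] - 1] = x;
    parent[y - 1] = parent[x - 1];
    if (!parent[x - 1]) root = y;
    else if (right[parent[x - 1] - 1] == x) right[parent[x - 1] - 1] = y;
    else left[parent[x - 1] - 1] = y;
    right[y - 1] = x;
    parent[x - 1] = y;
    update_maxend(x);
    update_maxend(y);
  }

  void insert(double s, double e, int i) {
    start_.push_back(s);
    end_.push_back(e);
    maxend.push_back(e);
    id.push_back(i);
    left.push_back(0);
    right.push_back(0);
    parent.push_back(0);
    red.push_back(1);
    int z = size();
    int y = 0, x = root;
    while (x) {
      y = x;
      maxend[x - 1] = std::max(maxend[x - 1], e);  // augmentation on the way down
      x = less(s, e, i, x) ? left[x - 1] : right[x - 1];
    }
    parent[z - 1] = y;
    if (!y) root = z;
    else if (less(s, e, i, y)) left[y - 1] = z;
    else right[y - 1] = z;
    // red-black fixup
    while (z != root && red[parent[z - 1] - 1]) {
      int p = parent[z - 1];
      int g = parent[p - 1];
      if (p == left[g - 1]) {
        int u = right[g - 1];
        if (u && red[u - 1]) {
          red[p - 1] = 0; red[u - 1] = 0; red[g - 1] = 1; z = g;
        } else {
          if (z == right[p - 1]) { z = p; rotate_left(z); p = parent[z - 1]; g = parent[p - 1]; }
          red[p - 1] = 0; red[g - 1] = 1;
          rotate_right(g);
        }
      } else {
        int u = left[g - 1];
        if (u && red[u - 1]) {
          red[p - 1] = 0; red[u - 1] = 0; red[g - 1] = 1; z = g;
        } else {
          if (z == left[p - 1]) { z = p; rotate_right(z); p = parent[z - 1]; g = parent[p - 1]; }
          red[p - 1] = 0; red[g - 1] = 1;
          rotate_left(g);
        }
      }
    }
    red[root - 1] = 0;
  }

  // returns black height, or -1 on any red-black / order / maxend violation
  int validate(int v, double lo_s, double lo_e, int lo_i, bool has_lo,
               double hi_s, double hi_e, int hi_i, bool has_hi) const {
    if (!v) return 1;
    double s = start_[v - 1], e = end_[v - 1];
    int i = id[v - 1];
    if (has_lo) {
      // (s,e,i) must be > (lo_s, lo_e, lo_i)
      bool gt = s > lo_s || (s == lo_s && (e > lo_e || (e == lo_e && i > lo_i)));
      if (!gt) return -1;
    }
    if (has_hi) {
      bool lt = s < hi_s || (s == hi_s && (e < hi_e || (e == hi_e && i < hi_i)));
      if (!lt) return -1;
    }
    if (red[v - 1]) {
      if (left[v - 1] && red[left[v - 1] - 1]) return -1;
      if (right[v - 1] && red[right[v - 1] - 1]) return -1;
    }
    if (left[v - 1] && parent[left[v - 1] - 1] != v) return -1;
    if (right[v - 1] && parent[right[v - 1] - 1] != v) return -1;
    double m = e;
    if (left[v - 1]) m = std::max(m, maxend[left[v - 1] - 1]);
    if (right[v - 1]) m = std::max(m, maxend[right[v - 1] - 1]);
    if (m != maxend[v - 1]) return -1;
    int bl = validate(left[v - 1], lo_s, lo_e, lo_i, has_lo, s, e, i, true);
    int br = validate(right[v - 1], s, e, i, true, hi_s, hi_e, hi_i, has_hi);
    if (bl < 0 || br < 0 || bl != br) return -1;
    return bl + (red[v - 1] ? 0 : 1);
  }

  bool ok() const {
    if (!root) return true;
    if (red[root - 1]) return false;
    return validate(root, 0, 0, 0, false, 0, 0, 0, false) >= 0;
  }

  List wrap_out() const {
    return List::create(
        _["root"] = root, _["start"] = wrap(start_), _["end"] = wrap(end_),
        _["max_end"] = wrap(maxend), _["id"] = wrap(id),
        _["left"] = wrap(left), _["right"] = wrap(right),
        _["parent"] = wrap(parent),
        _["color"] = wrap(std::vector<int>(red.begin(), red.end())));
  }
};

IT from_list(const List& t) {
  IT it;
  it.root = as<int>(t["root"]);
  it.start_ = as<std::vector<double>>(t["start"]);
  it.end_ = as<std::vector<double>>(t["end"]);
  it.maxend = as<std::vector<double>>(t["max_end"]);
  it.id = as<std::vector<int>>(t["id"]);
  it.left = as<std::vector<int>>(t["left"]);
  it.right = as<std::vector<int>>(t["right"]);
  it.parent = as<std::vector<int>>(t["parent"]);
  std::vector<int> col = as<std::vector<int>>(t["color"]);
  it.red.assign(col.begin(), col.end());
  return it;
}

}  // namespace

// [[Rcpp::export]]
List cpp_it_build(NumericVector starts, NumericVector ends, IntegerVector ids,
                  bool audit) {
  IT it;
  int violations = 0;
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    it.insert(starts[i], ends[i], ids[i]);
    if (audit && !it.ok()) ++violations;
  }
  List out = it.wrap_out();
  out["audit_violations"] = audit ? violations : NA_INTEGER;
  return out;
}

// [[Rcpp::export]]
bool cpp_it_validate(List tree) {
  return from_list(tree).ok();
}

// [[Rcpp::export]]
IntegerVector cpp_it_inorder(List tree) {
  IT it = from_list(tree);
  std::vector<int> out;
  std::vector<int> stack;
  int v = it.root;
  while (v || !stack.empty()) {
    while (v) { stack.push_back(v); v = it.left[v - 1]; }
    v = stack.back();
    stack.pop_back();
    out.push_back(it.id[v - 1]);
    v = it.right[v - 1];
  }
  return wrap(out);
}

// overlap query with max-end pruning: report ids of intervals with
// start <= qe and end >= qs; inspected counts interval examinations
// [[Rcpp::export]]
List cpp_it_overlap(List tree, double qs, double qe) {
  IT it = from_list(tree);
  std::vector<int> res;
  int inspected = 0;
  std::vector<int> stack;
  if (it.root) stack.push_back(it.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    ++inspected;
    int lc = it.left[v - 1], rc = it.right[v - 1];
    if (lc && it.maxend[lc - 1] >= qs) stack.push_back(lc);
    if (it.start_[v - 1] <= qe) {
      if (it.end_[v - 1] >= qs) res.push_back(it.id[v - 1]);
      if (rc && it.maxend[rc - 1] >= qs) stack.push_back(rc);
    }
  }
  std::sort(res.begin(), res.end());
  return List::create(_["ids"] = wrap(res), _["inspected"] = inspected);
}

// ordered traversal with pruning: intervals entirely before q (end < qs)
// [[Rcpp::export]]
List cpp_it_before(List tree, double qs) {
  IT it = from_list(tree);
  std::vector<int> res;
  int inspected = 0;
  std::vector<int> stack;
  if (it.root) stack.push_back(it.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (it.maxend[v - 1] < qs) {
      // entire subtree qualifies: report without per-node inspection
      std::vector<int> sub{v};
      while (!sub.empty()) {
        int u = sub.back();
        sub.pop_back();
        res.push_back(it.id[u - 1]);
        if (it.left[u - 1]) sub.push_back(it.left[u - 1]);
        if (it.right[u - 1]) sub.push_back(it.right[u - 1]);
      }
      continue;
    }
    ++inspected;
    if (it.end_[v - 1] < qs) res.push_back(it.id[v - 1]);
    if (it.left[v - 1]) stack.push_back(it.left[v - 1]);
    // right subtree can only hold results if some start there is < qs;
    // starts >= this node's start, so prune when start >= qs
    if (it.right[v - 1] && it.start_[v - 1] < qs)
      stack.push_back(it.right[v - 1]);
  }
  std::sort(res.begin(), res.end());
  return List::create(_["ids"] = wrap(res), _["inspected"] = inspected);
}

// ordered traversal with pruning: intervals entirely after q (start > qe)
// [[Rcpp::export]]
List cpp_it_after(List tree, double qe) {
  IT it = from_list(tree);
  std::vector<int> res;
  int inspected = 0;
  std::vector<int> stack;
  if (it.root) stack.push_back(it.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    ++inspected;
    if (it.start_[v - 1] > qe) {
      res.push_back(it.id[v - 1]);
      // all starts in the right subtree are >= this start > qe
      std::vector<int> sub;
      if (it.right[v - 1]) sub.push_back(it.right[v - 1]);
      while (!sub.empty()) {
        int u = sub.back();
        sub.pop_back();
        res.push_back(it.id[u - 1]);
        if (it.left[u - 1]) sub.push_back(it.left[u - 1]);
        if (it.right[u - 1]) sub.push_back(it.right[u - 1]);
      }
      if (it.left[v - 1]) stack.push_back(it.left[v - 1]);
    } else {
      if (it.right[v - 1]) stack.push_back(it.right[v - 1]);
    }
  }
  std::sort(res.begin(), res.end());
  return List::create(_["ids"] = wrap(res), _["inspected"] = inspected);
}
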