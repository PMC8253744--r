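#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// cached k*log2(k) (single-threaded under R); entropies over integer class
// counts reduce to differences of these terms
static std::vector<double> klog2k_tab{0.0, 0.0};
static inline double klog2k(int k) {
  while ((int)klog2k_tab.size() <= k) {
    int i = (int)klog2k_tab.size();
    klog2k_tab.push_back(i * std::log2((double)i));
  }
  return klog2k_tab[k];
}

// m * H(pos, neg): total (unnormalized) binary entropy of a node, in bits
static inline double wentropy(int pos, int neg) {
  return klog2k(pos + neg) - klog2k(pos) - klog2k(neg);
}

struct Split {
  int feature;      // 0-based; -1 = no split
  double threshold;
  double gain;
  double gain_ratio;
  bool used_fallback;
};

// Nodes carry, for every feature, the node's row indices pre-sorted by that
// feature's value; splits partition these lists stably, so no sorting ever
// happens below the root.
typedef std::vector<std::vector<int>> SortedLists;

// Best C4.5-style binary split over a node.
//
// Candidate cuts for a feature are the midpoints between consecutive
// distinct sorted values (each side holds at least one instance). Within a
// feature, candidates whose information gain falls below the feature's
// average candidate gain are screened out; the survivor with the highest
// gain ratio is the feature's proposal. Across features the proposal with
// the highest gain ratio wins; ties break toward the lower feature index,
// then the lower threshold (guaranteed by scan order).
//
// If no candidate anywhere has positive gain (e.g. an exact-XOR node) and
// `allow_fallback` is set, the most balanced admissible cut (maximum split
// information) is returned instead so that tree growth always progresses.
static Split best_split_impl(const NumericMatrix &X, const IntegerVector &y,
                             const SortedLists &sorted, bool allow_fallback) {
  const double EPS = 1e-12;
  int p = (int)sorted.size();
  int m = (int)sorted[0].size();
  Split best = {-1, NA_REAL, 0.0, -1.0, false};
  int fb_feat = -1;
  double fb_thr = NA_REAL, fb_si = -1.0;

  int tot_pos = 0;
  for (int i : sorted[0]) tot_pos += y[i];
  double w_root = wentropy(tot_pos, m - tot_pos);

  std::vector<double> cand_thr, cand_gain, cand_si;
  cand_thr.reserve(m); cand_gain.reserve(m); cand_si.reserve(m);

  for (int j = 0; j < p; ++j) {
    const std::vector<int> &ord = sorted[j];
    cand_thr.clear(); cand_gain.clear(); cand_si.clear();
    int cum_pos = 0;
    for (int i = 0; i < m - 1; ++i) {
      cum_pos += y[ord[i]];
      double xa = X(ord[i], j), xb = X(ord[i + 1], j);
      if (xa >= xb) continue; // not a boundary between distinct values
      int nl = i + 1, nr = m - nl;
      double gain = (w_root - wentropy(cum_pos, nl - cum_pos)
                            - wentropy(tot_pos - cum_pos,
                                       nr - (tot_pos - cum_pos))) / m;
      double si = (klog2k(m) - klog2k(nl) - klog2k(nr)) / m;
      double thr = (xa + xb) / 2.0;
      // when the midpoint of two adjacent representable values rounds up
      // to xb, fall back to xa so that "<= thr" genuinely separates them
      if (!(thr < xb)) thr = xa;
      cand_thr.push_back(thr);
      cand_gain.push_back(gain);
      cand_si.push_back(si);
    }
    if (cand_thr.empty()) continue;

    double avg_gain = 0.0;
    for (double g : cand_gain) avg_gain += g;
    avg_gain /= cand_gain.size();

    for (size_t c = 0; c < cand_thr.size(); ++c) {
      if (cand_gain[c] + EPS < avg_gain) continue; // admissibility screen
      if (cand_gain[c] > EPS) {
        double gr = cand_gain[c] / cand_si[c];
        if (gr > best.gain_ratio + EPS) {
          best.gain_ratio = gr;
          best.feature = j;
          best.threshold = cand_thr[c];
          best.gain = cand_gain[c];
        }
      }
      if (cand_si[c] > fb_si + EPS) {
        fb_si = cand_si[c];
        fb_feat = j;
        fb_thr = cand_thr[c];
      }
    }
  }

  if (best.feature < 0 && allow_fallback && fb_feat >= 0) {
    best.feature = fb_feat;
    best.threshold = fb_thr;
    best.gain = 0.0;
    best.gain_ratio = 0.0;
    best.used_fallback = true;
  }
  return best;
}

static SortedLists sort_rows(const NumericMatrix &X,
                             const std::vector<int> &rows) {
  int p = X.ncol();
  SortedLists sorted(p);
  for (int j = 0; j < p; ++j) {
    sorted[j] = rows;
    std::stable_sort(sorted[j].begin(), sorted[j].end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
  }
  return sorted;
}

// exposed for unit-level checks of the split chooser
// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, IntegerVector y, IntegerVector idx,
                    bool allow_fallback) {
  std::vector<int> rows(idx.begin(), idx.end());
  Split s = best_split_impl(X, y, sort_rows(X, rows), allow_fallback);
  return List::create(
    _["feature"] = s.feature + 1, // 1-based; 0 means no split
    _["threshold"] = s.threshold,
    _["gain"] = s.gain,
    _["gain_ratio"] = s.gain_ratio,
    _["used_fallback"] = s.used_fallback);
}

struct Node {
  SortedLists sorted;
  std::vector<int> cond_feat;      // 0-based feature per path condition
  std::vector<char> cond_le;       // 1 = "<=", 0 = ">"
  std::vector<double> cond_thr;
};

struct Leaf {
  std::vector<int> idx;
  std::vector<int> cond_feat;
  std::vector<char> cond_le;
  std::vector<double> cond_thr;
  int n_pos = 0, n_neg = 0;
};

// Grow one full unpruned partial tree depth-first. Returns the number of
// leaves and fills `best` with the pre-order-first leaf of maximum
// coverage. Expansion stops at purity, fewer than min_leaf instances, or
// when every feature is constant on the node.
static int grow_tree(const NumericMatrix &X, const IntegerVector &y,
                     SortedLists root_sorted, int min_leaf, Leaf &best) {
  int p = (int)root_sorted.size();
  std::vector<Node> stack;
  Node root;
  root.sorted = std::move(root_sorted);
  stack.push_back(std::move(root));
  int n_leaves = 0;
  best.idx.clear();

  while (!stack.empty()) {
    Node node = std::move(stack.back());
    stack.pop_back();
    int m = (int)node.sorted[0].size();
    int npos = 0;
    for (int i : node.sorted[0]) npos += y[i];
    bool is_leaf = (m < min_leaf) || npos == 0 || npos == m;
    Split s = {-1, NA_REAL, 0.0, -1.0, false};
    if (!is_leaf) {
      s = best_split_impl(X, y, node.sorted, true);
      is_leaf = (s.feature < 0); // all features constant on this node
    }
    if (is_leaf) {
      ++n_leaves;
      if (m > (int)best.idx.size()) { // strict: pre-order first wins ties
        best.idx = node.sorted[0];
        best.cond_feat = node.cond_feat;
        best.cond_le = node.cond_le;
        best.cond_thr = node.cond_thr;
        best.n_pos = npos;
        best.n_neg = m - npos;
      }
      continue;
    }
    Node left, right;
    left.sorted.resize(p);
    right.sorted.resize(p);
    for (int j = 0; j < p; ++j) {
      left.sorted[j].reserve(m);
      right.sorted[j].reserve(m);
      for (int i : node.sorted[j]) {
        if (X(i, s.feature) <= s.threshold) left.sorted[j].push_back(i);
        else right.sorted[j].push_back(i);
      }
    }
    if (left.sorted[0].empty() || right.sorted[0].empty()) {
      // defensive: a split that fails to separate would loop forever
      ++n_leaves;
      if (m > (int)best.idx.size()) {
        best.idx = node.sorted[0];
        best.cond_feat = node.cond_feat;
        best.cond_le = node.cond_le;
        best.cond_thr = node.cond_thr;
        best.n_pos = npos;
        best.n_neg = m - npos;
      }
      continue;
    }
    left.cond_feat = node.cond_feat;  left.cond_le = node.cond_le;
    left.cond_thr = node.cond_thr;
    right.cond_feat = std::move(node.cond_feat);
    right.cond_le = std::move(node.cond_le);
    right.cond_thr = std::move(node.cond_thr);
    left.cond_feat.push_back(s.feature);
    left.cond_le.push_back(1);
    left.cond_thr.push_back(s.threshold);
    right.cond_feat.push_back(s.feature);
    right.cond_le.push_back(0);
    right.cond_thr.push_back(s.threshold);
    // push right first so the left child is expanded first (pre-order)
    stack.push_back(std::move(right));
    stack.push_back(std::move(left));
  }
  return n_leaves;
}

// Separate-and-conquer rule induction: repeatedly grow a partial tree on
// the uncovered instances, extract its largest leaf as a rule, and remove
// the instances that leaf covers; a single-leaf tree terminates the loop
// and defines the default class counts. Returns rules with 0-based feature
// indices; condition paths are simplified on the R side.
// [[Rcpp::export]]
List part_fit_cpp(NumericMatrix X, IntegerVector y, int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  SortedLists global = sort_rows(X, all); // only sort ever performed
  std::vector<char> alive(n, 1);
  int n_remaining = n;

  List rules;
  int def_pos = 0, def_neg = 0;
  Leaf best;
  while (n_remaining > 0) {
    SortedLists node(p);
    for (int j = 0; j < p; ++j) {
      node[j].reserve(n_remaining);
      for (int i : global[j]) if (alive[i]) node[j].push_back(i);
    }
    int n_leaves = grow_tree(X, y, std::move(node), min_leaf, best);
    if (n_leaves <= 1) {
      for (int i = 0; i < n; ++i) {
        if (alive[i]) { if (y[i]) ++def_pos; else ++def_neg; }
      }
      break;
    }
    int nc = (int)best.cond_feat.size();
    LogicalVector cl(nc);
    for (int i = 0; i < nc; ++i) cl[i] = best.cond_le[i] != 0;
    rules.push_back(List::create(
      _["feature"] = IntegerVector(best.cond_feat.begin(),
                                   best.cond_feat.end()),
      _["le"] = cl,
      _["threshold"] = NumericVector(best.cond_thr.begin(),
                                     best.cond_thr.end()),
      _["n_covered"] = (int)best.idx.size(),
      _["n_pos"] = best.n_pos,
      _["n_neg"] = best.n_neg));
    for (int i : best.idx) alive[i] = 0;
    n_remaining -= (int)best.idx.size();
  }
  return List::create(_["rules"] = rules,
                      _["default_pos"] = def_pos,
                      _["default_neg"] = def_neg);
}
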