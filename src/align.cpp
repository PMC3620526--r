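#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh). A gap of length L costs
// gap_open + L * gap_extend, matching the convention of common pairwise
// aligners. Returns the optimal score and a run-length encoded operation
// list over alignment columns: M (both), I (base only in b), D (base only
// in a).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -2.0,
                  double gap_open = 4.0, double gap_extend = 1.0) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  if ((double)(n + 1) * (double)(m + 1) > 6e7)
    stop("alignment segment too large for full dynamic programming");

  std::vector<double> Mrow((m + 1)), Xrow(m + 1), Yrow(m + 1);
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  // traceback: 0 from M, 1 from X (gap in b / consumes a), 2 from Y
  std::vector<unsigned char> tbM((n + 1) * (size_t)(m + 1));
  std::vector<unsigned char> tbX((n + 1) * (size_t)(m + 1));
  std::vector<unsigned char> tbY((n + 1) * (size_t)(m + 1));
  const size_t W = m + 1;

  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = -(gap_open + j * gap_extend);
    tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    Mrow[0] = NEG;
    Yrow[0] = NEG;
    Xrow[0] = -(gap_open + i * gap_extend);
    tbX[i * W] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      double best = Mprev[j - 1]; unsigned char arg = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; arg = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; arg = 2; }
      Mrow[j] = best + s; tbM[i * W + j] = arg;
      // X: gap in b, consumes a (move down)
      double openx = Mprev[j] - (gap_open + gap_extend);
      double extx  = Xprev[j] - gap_extend;
      if (openx >= extx) { Xrow[j] = openx; tbX[i * W + j] = 0; }
      else               { Xrow[j] = extx;  tbX[i * W + j] = 1; }
      // Y: gap in a, consumes b (move right)
      double openy = Mrow[j - 1] - (gap_open + gap_extend);
      double exty  = Yrow[j - 1] - gap_extend;
      if (openy >= exty) { Yrow[j] = openy; tbY[i * W + j] = 0; }
      else               { Yrow[j] = exty;  tbY[i * W + j] = 2; }
    }
    std::swap(Mprev, Mrow); std::swap(Xprev, Xrow); std::swap(Yprev, Yrow);
  }
  double scoreM = Mprev[m], scoreX = Xprev[m], scoreY = Yprev[m];
  double score = scoreM; int state = 0;
  if (scoreX > score) { score = scoreX; state = 1; }
  if (scoreY > score) { score = scoreY; state = 2; }

  // traceback
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tbM[(size_t)i * W + j];
      ops.push_back('M'); --i; --j; state = prev;
    } else if (state == 1) {
      unsigned char prev = tbX[(size_t)i * W + j];
      ops.push_back('D'); --i; state = prev;
    } else {
      unsigned char prev = tbY[(size_t)i * W + j];
      ops.push_back('I'); --j; state = prev;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<std::string> vals; std::vector<int> lens;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (vals.empty() || vals.back()[0] != ops[k]) {
      vals.push_back(std::string(1, ops[k])); lens.push_back(1);
    } else {
      ++lens.back();
    }
  }
  return List::create(_["score"] = score,
                      _["op"] = wrap(vals), _["len"] = wrap(lens));
}

// Greedy longest-first co-linear chaining of anchors. Anchors are exact
// matches (sa, sb, len) in 0-based coordinates; ties on length broken by
// leftmost a-position. An anchor is accepted iff its start coordinates are
// co-linear (non-decreasing in both genomes) with every anchor accepted so
// far; overlaps between accepted anchors are permitted and trimmed during
// alignment assembly. Returns a logical keep mask.
// [[Rcpp::export(name = ".chain_anchors_cpp")]]
LogicalVector chain_anchors_cpp(IntegerVector sa, IntegerVector sb,
                                IntegerVector len) {
  const int n = sa.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (len[x] != len[y]) return len[x] > len[y];
    return sa[x] < sa[y];
  });
  std::map<int, std::pair<int, int> > acc;  // a-start -> (b-start, len)
  LogicalVector keep(n, false);
  for (int idx : ord) {
    int a0 = sa[idx], b0 = sb[idx], L = len[idx];
    bool ok = true;
    auto it = acc.lower_bound(a0);
    if (it != acc.end()) {  // next anchor (a-start >= a0)
      if (it->first == a0 || b0 > it->second.first) ok = false;
    }
    if (ok && it != acc.begin()) {
      auto pv = std::prev(it);
      if (pv->second.first > b0) ok = false;
      // containment in the previous anchor adds nothing
      if (pv->first + pv->second.second >= a0 + L &&
          pv->second.first + pv->second.second >= b0 + L) ok = false;
    }
    if (ok) {
      acc[a0] = std::make_pair(b0, L);
      keep[idx] = true;
    }
  }
  return keep;
}
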