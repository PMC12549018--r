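#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history complexity: the number of phrases in
// the factorization where each phrase is the shortest prefix of the
// remaining string that cannot be reproduced (with self-overlap allowed)
// from an earlier starting position. The phrase starting at position i has
// length LPF[i] + 1 (truncated at the end of the string), where LPF is the
// longest-previous-factor array. LPF[i] is the larger of the lcp values
// between suffix i and its nearest neighbours in suffix-array order that
// start earlier in the text; lcp queries are answered by range-minimum over
// the Kasai LCP array. Near-linearithmic overall, which matters for the
// long and highly repetitive rasters produced by coherent network states.

static void suffix_array(const std::vector<int> &s, std::vector<int> &sa) {
  const int n = (int)s.size();
  sa.resize(n);
  std::vector<int> rank_(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank_[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank_[a] != rank_[b]) return rank_[a] < rank_[b];
      int ra = a + k < n ? rank_[a + k] : -1;
      int rb = b + k < n ? rank_[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank_ = tmp;
    if (rank_[sa[n - 1]] == n - 1) break;
  }
}

// [[Rcpp::export(name = ".lz76_cpp")]]
double lz76_cpp(IntegerVector sv) {
  const int n = (int)sv.size();
  if (n == 0) return 0.0;
  if (n == 1) return 1.0;
  std::vector<int> s(sv.begin(), sv.end());
  std::vector<int> sa;
  suffix_array(s, sa);
  std::vector<int> rank_(n);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;

  // Kasai: lcp[r] = lcp(suffix sa[r-1], suffix sa[r]), lcp[0] = 0
  std::vector<int> lcp(n, 0);
  for (int i = 0, h = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }

  // sparse table for range-minimum over lcp[l+1 .. r] (lcp between the
  // suffixes at ranks l and r)
  int LOG = 1;
  while ((1 << LOG) < n) ++LOG;
  std::vector<std::vector<int>> st(LOG + 1);
  st[0] = lcp;
  for (int j = 1; j <= LOG; ++j) {
    int len = n - (1 << j) + 1;
    if (len <= 0) break;
    st[j].resize(len);
    for (int i = 0; i < len; ++i)
      st[j][i] = std::min(st[j - 1][i], st[j - 1][i + (1 << (j - 1))]);
  }
  std::vector<int> lg(n + 1, 0);
  for (int i = 2; i <= n; ++i) lg[i] = lg[i / 2] + 1;
  auto lcp_rank = [&](int rl, int rr) { // rl < rr
    int l = rl + 1, r = rr;
    int k = lg[r - l + 1];
    return std::min(st[k][l], st[k][r - (1 << k) + 1]);
  };

  // nearest earlier-starting suffixes in SA order: delete positions from
  // a doubly linked list over SA in decreasing text order
  std::vector<int> prev_occ(n, -1), next_occ(n, -1);
  {
    std::vector<int> lft(n), rgt(n);
    for (int i = 0; i < n; ++i) { lft[i] = i - 1; rgt[i] = i + 1; }
    for (int pos = n - 1; pos >= 0; --pos) {
      int r = rank_[pos];
      int l = lft[r], g = rgt[r];
      prev_occ[pos] = (l >= 0) ? sa[l] : -1;
      next_occ[pos] = (g < n) ? sa[g] : -1;
      if (l >= 0) rgt[l] = g;
      if (g < n) lft[g] = l;
    }
  }

  double c = 0.0;
  long pos = 0;
  while (pos < n) {
    int best = 0;
    int a = prev_occ[pos];
    if (a >= 0) {
      int la = lcp_rank(std::min(rank_[a], rank_[pos]),
                        std::max(rank_[a], rank_[pos]));
      if (la > best) best = la;
    }
    int b = next_occ[pos];
    if (b >= 0) {
      int lb = lcp_rank(std::min(rank_[b], rank_[pos]),
                        std::max(rank_[b], rank_[pos]));
      if (lb > best) best = lb;
    }
    pos += best + 1;
    c += 1.0;
  }
  return c;
}
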