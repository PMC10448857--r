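#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend detection of ungapped local similarity blocks with
// optional stitching of collinear extensions across small indels.
// Scores: match/mismatch as given; N matches nothing (always a mismatch
// for scoring and never a match for identity counts).

namespace {

struct Hsp {
  int qs, qe, ss, se;   // 0-based half-open, on the working (possibly rc) subject
  int matches;          // identical non-N columns
  int cols;             // alignment columns incl. gap columns
  int score;
};

inline int sc(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

inline bool is_match(char a, char b) {
  return a != 'N' && b != 'N' && a == b;
}

// encode k-mer over ACGT; returns false if any N/other
inline bool encode_kmer(const char* s, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false;
    }
    code = (code << 2) | (uint64_t)v;
  }
  return true;
}

void extend_seed(const std::string& a, const std::string& b, int i, int j,
                 int k, int match, int mismatch, int xdrop, Hsp& out) {
  const int m = (int)a.size(), n = (int)b.size();
  int cur = k * match, best = cur;
  int qe = i + k, se = j + k;
  // right extension
  {
    int ii = i + k, jj = j + k, run = cur, top = cur, be = i + k;
    while (ii < m && jj < n) {
      run += sc(a[ii], b[jj], match, mismatch);
      if (run > top) { top = run; be = ii + 1; }
      if (top - run > xdrop) break;
      ++ii; ++jj;
    }
    best = top; qe = be; se = j + (be - i);
  }
  // left extension
  int qs = i, ss = j;
  {
    int ii = i - 1, jj = j - 1, run = best, top = best, bs = i;
    while (ii >= 0 && jj >= 0) {
      run += sc(a[ii], b[jj], match, mismatch);
      if (run > top) { top = run; bs = ii; }
      if (top - run > xdrop) break;
      --ii; --jj;
    }
    best = top; qs = bs; ss = j - (i - bs);
  }
  int matches = 0;
  for (int t = 0; t < qe - qs; ++t) {
    if (is_match(a[qs + t], b[ss + t])) ++matches;
  }
  out.qs = qs; out.qe = qe; out.ss = ss; out.se = se;
  out.matches = matches; out.cols = qe - qs; out.score = best;
}

std::vector<Hsp> find_hsps(const std::string& a, const std::string& b,
                           int k, int match, int mismatch, int xdrop) {
  std::vector<Hsp> hsps;
  const int m = (int)a.size(), n = (int)b.size();
  if (k > m || k > n) return hsps;

  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(n);
  for (int j = 0; j + k <= n; ++j) {
    uint64_t code;
    if (encode_kmer(b.data() + j, k, code)) index[code].push_back(j);
  }
  // furthest query end already extended per diagonal (d = i - j)
  std::unordered_map<long long, int> diag_cap;

  for (int i = 0; i + k <= m; ++i) {
    uint64_t code;
    if (!encode_kmer(a.data() + i, k, code)) continue;
    auto it = index.find(code);
    if (it == index.end()) continue;
    for (int j : it->second) {
      long long d = (long long)i - (long long)j;
      auto cap = diag_cap.find(d);
      if (cap != diag_cap.end() && i + k <= cap->second) continue;
      Hsp h;
      extend_seed(a, b, i, j, k, match, mismatch, xdrop, h);
      diag_cap[d] = h.qe;
      hsps.push_back(h);
    }
  }

  // On promising diagonals, the X-drop heuristic may stop short of the
  // optimal ungapped segment; recompute it exactly (maximum subarray over
  // the whole diagonal), which equals Smith-Waterman restricted to that
  // diagonal. Spurious seeds rarely pass the score trigger, keeping this
  // pass cheap.
  {
    const int trigger = k + 2;
    std::unordered_map<long long, int> diag_best;
    for (const Hsp& h : hsps) {
      long long d = (long long)h.qs - h.ss;
      auto it = diag_best.find(d);
      if (it == diag_best.end() || h.score > it->second) diag_best[d] = h.score;
    }
    for (const auto& kv : diag_best) {
      if (kv.second < trigger) continue;
      long long d = kv.first;
      int i0 = d > 0 ? (int)d : 0;
      int j0 = d > 0 ? 0 : (int)(-d);
      int len = std::min(m - i0, n - j0);
      int best = 0, bs = 0, be = 0, cur = 0, cs = 0;
      for (int t = 0; t < len; ++t) {
        int s = sc(a[i0 + t], b[j0 + t], match, mismatch);
        if (cur <= 0) { cur = s; cs = t; }
        else cur += s;
        if (cur > best) { best = cur; bs = cs; be = t + 1; }
      }
      if (best <= 0 || be - bs < k) continue;
      Hsp h;
      h.qs = i0 + bs; h.qe = i0 + be;
      h.ss = j0 + bs; h.se = j0 + be;
      h.matches = 0;
      for (int t = bs; t < be; ++t) {
        if (is_match(a[i0 + t], b[j0 + t])) ++h.matches;
      }
      h.cols = be - bs; h.score = best;
      hsps.push_back(h);
    }
  }

  // merge overlapping blocks on the same diagonal, keeping the higher score
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& x, const Hsp& y) {
    long long dx = (long long)x.qs - x.ss, dy = (long long)y.qs - y.ss;
    if (dx != dy) return dx < dy;
    if (x.qs != y.qs) return x.qs < y.qs;
    return x.score > y.score;
  });
  std::vector<Hsp> merged;
  for (const Hsp& h : hsps) {
    if (!merged.empty()) {
      Hsp& p = merged.back();
      long long dp = (long long)p.qs - p.ss, dh = (long long)h.qs - h.ss;
      if (dp == dh && h.qs < p.qe) {
        if (h.score > p.score) p = h;
        continue;
      }
    }
    merged.push_back(h);
  }
  return merged;
}

// stitch collinear extensions across small indels (single gap at junction)
void stitch(std::vector<Hsp>& hsps, const std::string& a, const std::string& b,
            int match, int mismatch, int gap_open, int gap_extend, int band) {
  if (hsps.size() < 2) return;
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& x, const Hsp& y) {
    if (x.qs != y.qs) return x.qs < y.qs;
    return x.ss < y.ss;
  });
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t u = 0; u + 1 < hsps.size() && !changed; ++u) {
      for (size_t v = u + 1; v < hsps.size(); ++v) {
        Hsp& A = hsps[u];
        Hsp& B = hsps[v];
        int qgap = B.qs - A.qe, sgap = B.ss - A.se;
        if (qgap < 0 || sgap < 0) continue;
        int shift = qgap - sgap;              // net indel length (0: mismatch bridge)
        if (std::abs(shift) > band) continue;
        int bridge = std::min(qgap, sgap);
        if (bridge > (shift == 0 ? 256 : 4 * band)) continue;
        // bridge aligned ungapped adjacent to A; single gap of |shift| columns
        int bm = 0, bs = 0;
        for (int t = 0; t < bridge; ++t) {
          char ca = a[A.qe + t], cb = b[A.se + t];
          bs += sc(ca, cb, match, mismatch);
          if (is_match(ca, cb)) ++bm;
        }
        int gs = shift == 0 ? 0 : gap_open + gap_extend * (std::abs(shift) - 1);
        int total = A.score + B.score + bs + gs;
        if (total > A.score && total > B.score) {
          Hsp merged;
          merged.qs = A.qs; merged.qe = B.qe;
          merged.ss = A.ss; merged.se = B.se;
          merged.matches = A.matches + B.matches + bm;
          merged.cols = A.cols + B.cols + bridge + std::abs(shift);
          merged.score = total;
          hsps[u] = merged;
          hsps.erase(hsps.begin() + v);
          changed = true;
          break;
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_find_blocks(std::string a, std::string b, int k, int match,
                          int mismatch, int xdrop, int gap_open,
                          int gap_extend, int band, bool do_stitch) {
  std::vector<Hsp> hsps = find_hsps(a, b, k, match, mismatch, xdrop);
  if (do_stitch) stitch(hsps, a, b, match, mismatch, gap_open, gap_extend, band);
  int n = (int)hsps.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), matches(n), cols(n), score(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hsps[i].qs; qe[i] = hsps[i].qe;
    ss[i] = hsps[i].ss; se[i] = hsps[i].se;
    matches[i] = hsps[i].matches; cols[i] = hsps[i].cols;
    score[i] = hsps[i].score;
  }
  return DataFrame::create(_["qs"] = qs, _["qe"] = qe, _["ss"] = ss,
                           _["se"] = se, _["matches"] = matches,
                           _["cols"] = cols, _["score"] = score);
}
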