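#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment in the cross_match convention: a gap of
// length L costs gap_open + (L-1) * gap_extend (both negative scores).

struct AlnResult {
  int score;          // best local score
  int a_start, a_end; // 0-based half-open on sequence a
  int b_start, b_end; // 0-based half-open on sequence b
  int mismatches;     // substitution columns
  int aligned_cols;   // match + mismatch columns (gaps excluded)
};

static inline int base_score(char a, char b, int match, int mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// Full Smith-Waterman with affine gaps and traceback of the single best
// local alignment. Quadratic in the product of lengths; callers keep the
// windows small (a few hundred nt).
static AlnResult smith_waterman(const std::string &a, const std::string &b,
                                int match, int mismatch,
                                int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  AlnResult res{0, 0, 0, 0, 0, 0, 0};
  if (n == 0 || m == 0) return res;

  // M: ends in (mis)match; X: gap in b (consumes a); Y: gap in a (consumes b)
  std::vector<int> Mrow((m + 1), 0), Xrow((m + 1), NEG), Yrow((m + 1), NEG);
  std::vector<int> Mprev((m + 1), 0), Xprev((m + 1), NEG), Yprev((m + 1), NEG);
  // traceback matrices: 0 stop, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0),
      tbX((size_t)(n + 1) * (m + 1), 0), tbY((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Mrow[0] = 0; Xrow[0] = NEG; Yrow[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * (m + 1) + j;
      // gap in b: vertical move, consumes a[i-1]
      int x_open = Mprev[j] + gap_open;
      int x_ext  = Xprev[j] + gap_extend;
      if (x_open >= x_ext) { Xrow[j] = x_open; tbX[idx] = 1; }
      else                 { Xrow[j] = x_ext;  tbX[idx] = 2; }
      // gap in a: horizontal move, consumes b[j-1]
      int y_open = Mrow[j - 1] + gap_open;
      int y_ext  = Yrow[j - 1] + gap_extend;
      if (y_open >= y_ext) { Yrow[j] = y_open; tbY[idx] = 1; }
      else                 { Yrow[j] = y_ext;  tbY[idx] = 3; }
      // match/mismatch; dv = best predecessor, 0 = start a new alignment
      int s = base_score(a[i - 1], b[j - 1], match, mismatch);
      int diagM = Mprev[j - 1], diagX = Xprev[j - 1], diagY = Yprev[j - 1];
      int from = 1, dv = diagM;
      if (diagX > dv) { dv = diagX; from = 2; }
      if (diagY > dv) { dv = diagY; from = 3; }
      if (dv <= 0) { dv = 0; from = 0; }
      int mval = dv + s;
      if (mval < 0) { mval = 0; from = 0; }
      Mrow[j] = mval; tbM[idx] = (unsigned char)from;
      if (Mrow[j] > best) { best = Mrow[j]; bi = i; bj = j; }
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }

  if (best <= 0) return res;
  // traceback from (bi, bj) in state M
  int i = bi, j = bj, state = 1; // 1=M, 2=X, 3=Y
  int mism = 0, cols = 0;
  int a_end = bi, b_end = bj, a_start = bi, b_start = bj;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (m + 1) + j;
    if (state == 1) {
      ++cols;
      if (a[i - 1] != b[j - 1] || a[i - 1] == 'N') ++mism;
      int from = tbM[idx];
      --i; --j;
      a_start = i; b_start = j;
      if (from == 0) break;
      state = from;
    } else if (state == 2) {
      int from = tbX[idx];
      --i;
      state = from;
    } else {
      int from = tbY[idx];
      --j;
      state = from;
    }
  }
  res.score = best;
  res.a_start = a_start; res.a_end = a_end;
  res.b_start = b_start; res.b_end = b_end;
  res.mismatches = mism; res.aligned_cols = cols;
  return res;
}

// [[Rcpp::export(name = ".cpp_smith_waterman")]]
List cpp_smith_waterman(std::string a, std::string b,
                        int match, int mismatch, int gap_open, int gap_extend) {
  AlnResult r = smith_waterman(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = r.score,
                      _["a_start"] = r.a_start, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_start, _["b_end"] = r.b_end,
                      _["mismatches"] = r.mismatches,
                      _["aligned_cols"] = r.aligned_cols);
}

static inline bool kmer_code(const std::string &s, int pos, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t v;
    switch (s[pos + i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: return false;
    }
    code = (code << 2) | v;
  }
  return true;
}

// Seed-and-extend scan of one query against one consensus (one strand).
// Exact seed_k-mer hits are clustered by diagonal; each cluster is
// realigned with full local SW inside a window around the projected
// consensus placement, so the reported score is the true local-alignment
// optimum for that interval.
// [[Rcpp::export(name = ".cpp_seed_scan")]]
DataFrame cpp_seed_scan(std::string query, std::string consensus,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int seed_k, int band, int min_score, int min_length) {
  const int n = (int)query.size(), clen = (int)consensus.size();
  std::vector<int> qstart, qend, score, mismatches, cols;
  if (n < seed_k || clen < seed_k) {
    return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                             _["score"] = score, _["mismatches"] = mismatches,
                             _["aligned_cols"] = cols);
  }
  // hash consensus k-mers
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve(clen * 2);
  for (int c = 0; c + seed_k <= clen; ++c) {
    uint64_t code;
    if (kmer_code(consensus, c, seed_k, code)) index[code].push_back(c);
  }
  // collect seeds as (diagonal, query position)
  std::vector<std::pair<int, int>> seeds;
  for (int i = 0; i + seed_k <= n; ++i) {
    uint64_t code;
    if (!kmer_code(query, i, seed_k, code)) continue;
    auto it = index.find(code);
    if (it == index.end()) continue;
    for (int c : it->second) seeds.push_back(std::make_pair(i - c, i));
  }
  if (seeds.empty()) {
    return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                             _["score"] = score, _["mismatches"] = mismatches,
                             _["aligned_cols"] = cols);
  }
  std::sort(seeds.begin(), seeds.end());
  // cluster seeds: same cluster while diagonal within band and query
  // positions within one consensus length of the previous seed
  std::vector<std::pair<int, int>> cluster_bounds; // (diag_lo, diag_hi) unused; store window
  size_t s0 = 0;
  std::vector<std::pair<int, int>> windows; // query windows [lo, hi)
  for (size_t s = 1; s <= seeds.size(); ++s) {
    bool flush = (s == seeds.size());
    if (!flush) {
      const auto &prev = seeds[s - 1];
      const auto &cur = seeds[s];
      if (cur.first - seeds[s0].first > band ||
          (cur.first == prev.first && cur.second - prev.second > clen) )
        flush = true;
      if (cur.first - prev.first > band) flush = true;
    }
    if (flush) {
      int dlo = seeds[s0].first, dhi = seeds[s - 1].first;
      int lo = std::max(0, dlo - band);
      int hi = std::min(n, dhi + clen + band);
      windows.push_back(std::make_pair(lo, hi));
      s0 = s;
    }
  }
  // merge overlapping windows (duplicate clusters from the same copy)
  std::sort(windows.begin(), windows.end());
  std::vector<std::pair<int, int>> merged;
  for (auto &w : windows) {
    if (!merged.empty() && w.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, w.second);
    else merged.push_back(w);
  }
  for (auto &w : merged) {
    std::string window = query.substr(w.first, w.second - w.first);
    AlnResult r = smith_waterman(window, consensus, match, mismatch,
                                 gap_open, gap_extend);
    if (r.score >= min_score && (r.a_end - r.a_start) >= min_length) {
      qstart.push_back(w.first + r.a_start);
      qend.push_back(w.first + r.a_end);
      score.push_back(r.score);
      mismatches.push_back(r.mismatches);
      cols.push_back(r.aligned_cols);
    }
  }
  return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                           _["score"] = score, _["mismatches"] = mismatches,
                           _["aligned_cols"] = cols);
}
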