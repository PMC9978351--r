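#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <functional>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Mott quality trimming: for each read find the contiguous segment maximising
// sum(limit - perr(base)). Returns 1-based [start, end]; start 0 => discard.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_mott_bounds(CharacterVector qual, double limit, int offset) {
  const int n = qual.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(qual, r));
    int len = LENGTH(STRING_ELT(qual, r));
    double cur = 0.0, best = 0.0;
    int cur_start = 0, best_start = 0, best_end = -1;
    for (int i = 0; i < len; ++i) {
      int phred = (int)q[i] - offset;
      double perr = std::pow(10.0, -phred / 10.0);
      cur += limit - perr;
      if (cur <= 0.0) {
        cur = 0.0;
        cur_start = i + 1;
      } else {
        int curlen = i - cur_start + 1;
        int blen = best_end - best_start + 1;
        if (cur > best + 1e-12 ||
            (std::abs(cur - best) <= 1e-12 && curlen > blen)) {
          best = cur;
          best_start = cur_start;
          best_end = i;
        }
      }
    }
    if (best_end < best_start) {
      out(r, 0) = 0; out(r, 1) = -1;
    } else {
      out(r, 0) = best_start + 1; out(r, 1) = best_end + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random substitution errors using R's RNG (respects set.seed()).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    buf.assign(s, len);
    for (int i = 0; i < len; ++i) {
      if (unif_rand() < rate) {
        char cur = buf[i];
        char sub = cur;
        while (sub == cur)
          sub = bases[(int)(unif_rand() * 4) & 3];
        buf[i] = sub;
      }
    }
    out[r] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer seed-and-extend read mapper.
// ---------------------------------------------------------------------------

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Hit { int ref; int diag; };
struct Cand { int ref; int diag; int votes; };

struct Placement {
  int ref; long start; int strand; // start 0-based on forward reference
  int score, qlen, cols, matches;
};

// banded Smith-Waterman of query vs window; query row i is expected near
// window column i + band. Band-local row recurrence with a traceback
// matrix of width 2*band+1 (codes 0 stop, 1 diag, 2 up, 3 left).
static bool banded_sw(const std::vector<int8_t> &qb, const char *w, int wlen,
                      int band, int match, int mismatch, int gap,
                      Placement &pl, long ws /*window start on ref*/) {
  const int m = (int)qb.size();
  const int width = 2 * band + 1;
  if (wlen <= 0) return false;
  std::vector<int8_t> wb(wlen);
  for (int j = 0; j < wlen; ++j) wb[j] = (int8_t)base2bit(w[j]);
  // rows indexed by off = j - i in [0, 2*band]; +1 shift for sentinels
  std::vector<int> Hp(width + 2, 0), Hc(width + 2, 0);
  std::vector<uint8_t> tb((size_t)(m + 1) * width, 0);
  int best = 0, bi = -1, boff = -1;
  for (int i = 1; i <= m && i <= wlen; ++i) {
    const int offmax = std::min(width - 1, wlen - i);
    const int8_t qc = qb[i - 1];
    uint8_t *tbrow = &tb[(size_t)i * width];
    Hc[0] = 0; // sentinel for off-1 at off=0
    int *hc = Hc.data() + 1, *hp = Hp.data() + 1;
    hp[width] = 0; // sentinel for off+1 at off=width-1
    const int8_t *wrow = wb.data() + (i - 1); // wb[i-1+off] for col j-1... j=i+off -> wb[j-1]=wb[i+off-1]
    for (int off = 0; off <= offmax; ++off) {
      int s = (qc >= 0 && qc == wrow[off]) ? match : mismatch;
      int vd = hp[off] + s;
      int vu = hp[off + 1] + gap;
      int vl = hc[off - 1] + gap;
      int v = vd;
      uint8_t t = 1;
      if (vu > v) { v = vu; t = 2; }
      if (vl > v) { v = vl; t = 3; }
      if (v <= 0) { v = 0; t = 0; }
      hc[off] = v;
      tbrow[off] = t;
      if (v > best) { best = v; bi = i; boff = off; }
    }
    for (int off = offmax + 1; off < width; ++off) { hc[off] = 0; tbrow[off] = 0; }
    std::swap(Hp, Hc);
  }
  if (best <= 0) return false;
  // traceback from (bi, boff)
  int i = bi, off = boff, matches = 0, cols = 0;
  int qend = bi, qstart = bi, jstart = bi + boff;
  while (i > 0) {
    uint8_t t = tb[(size_t)i * width + off];
    if (t == 0) break;
    int j = i + off;
    if (t == 1) {
      ++cols;
      if (qb[i - 1] >= 0 && qb[i - 1] == wb[j - 1]) ++matches;
      qstart = i; jstart = j;
      --i; // off unchanged: (i-1, j-1)
    } else if (t == 2) { ++cols; qstart = i; --i; ++off; } // (i-1, j)
    else { ++cols; jstart = j; --off; }                    // (i, j-1)
    if (off < 0 || off >= width) break;
  }
  pl.score = best;
  pl.qlen = qend - qstart + 1;
  pl.cols = cols;
  pl.matches = matches;
  pl.start = ws + (jstart - 1);
  return true;
}

static void collect_candidates(
    const std::vector<int8_t> &qb, int k, int step,
    const std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> &idx,
    int band, std::vector<Cand> &cands) {
  const int m = (int)qb.size();
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int off = 0; off + k <= m; off += step) {
    uint64_t key = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int8_t b = qb[off + t];
      if (b < 0) { ok = false; break; }
      key = ((key << 2) | (uint64_t)b) & mask;
    }
    if (!ok) continue;
    auto it = idx.find(key);
    if (it == idx.end()) continue;
    if (it->second.size() > 512) continue; // over-represented k-mer
    for (auto &p : it->second) {
      int diag = p.second - off;
      bool found = false;
      for (auto &c : cands)
        if (c.ref == p.first && std::abs(diag - c.diag) <= band) {
          ++c.votes; found = true; break;
        }
      if (!found && cands.size() < 64) cands.push_back({p.first, diag, 1});
    }
  }
  std::sort(cands.begin(), cands.end(),
            [](const Cand &a, const Cand &b) { return a.votes > b.votes; });
  if (cands.size() > 24) cands.resize(24);
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector ref_seqs, LogicalVector circular,
                        CharacterVector reads, int k, int seed_step,
                        double length_fraction, double similarity_fraction,
                        int match, int mismatch, int gap, int band,
                        int max_hits) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref), ext(nref);
  std::vector<long> reflen(nref);
  int max_read = 0;
  for (int r = 0; r < reads.size(); ++r)
    max_read = std::max(max_read, (int)LENGTH(STRING_ELT(reads, r)));
  const int extlen = max_read + 2 * band + 2;
  for (int r = 0; r < nref; ++r) {
    refs[r] = std::string(CHAR(STRING_ELT(ref_seqs, r)));
    reflen[r] = (long)refs[r].size();
    ext[r] = refs[r];
    if (circular[r])
      ext[r] += refs[r].substr(0, std::min<long>(reflen[r], extlen));
  }
  // index: kmer -> (ref, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int r = 0; r < nref; ++r) {
    long lastpos = circular[r] ? reflen[r] - 1 : reflen[r] - k;
    if (lastpos < 0) continue;
    for (long pos = 0; pos <= lastpos; ++pos) {
      if (pos + k > (long)ext[r].size()) break;
      uint64_t key = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int b = base2bit(ext[r][pos + t]);
        if (b < 0) { ok = false; break; }
        key = ((key << 2) | (uint64_t)b) & mask;
      }
      if (ok) idx[key].push_back({r, (int)pos});
    }
  }

  std::vector<int> o_read, o_ref, o_strand, o_score, o_qlen, o_cols, o_match;
  std::vector<double> o_start;

  for (int rd = 0; rd < reads.size(); ++rd) {
    std::string fwd(CHAR(STRING_ELT(reads, rd)));
    const int m = (int)fwd.size();
    if (m < k) continue;
    std::vector<Placement> pls;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp(fwd);
      std::vector<int8_t> qb(m);
      for (int t = 0; t < m; ++t) qb[t] = (int8_t)base2bit(q[t]);
      std::vector<Cand> cands;
      collect_candidates(qb, k, seed_step, idx, band, cands);
      for (auto &c : cands) {
        long d = c.diag;
        long ws = d - band; // 0-based window start on extended ref
        const std::string &E = ext[c.ref];
        long we = std::min<long>((long)E.size(), d + m + band);
        if (ws < 0) ws = 0;
        if (we - ws < k) continue;
        Placement pl;
        pl.ref = c.ref; pl.strand = strand;
        if (!banded_sw(qb, E.c_str() + ws, (int)(we - ws), band, match,
                       mismatch, gap, pl, ws))
          continue;
        if ((double)pl.qlen / m < length_fraction) continue;
        if (pl.cols <= 0 || (double)pl.matches / pl.cols < similarity_fraction)
          continue;
        pls.push_back(pl);
      }
    }
    if (pls.empty()) continue;
    int best = 0;
    for (auto &p : pls) best = std::max(best, p.score);
    // dedupe on (ref, start mod len, strand), keep best-scoring ties
    std::vector<Placement> keep;
    for (auto &p : pls) {
      if (p.score != best) continue;
      long start = p.start % reflen[p.ref];
      bool dup = false;
      for (auto &kp : keep)
        if (kp.ref == p.ref && kp.strand == p.strand &&
            kp.start == start) { dup = true; break; }
      if (!dup) {
        Placement q2 = p; q2.start = start;
        keep.push_back(q2);
      }
    }
    if ((int)keep.size() > max_hits) keep.resize(max_hits);
    for (auto &p : keep) {
      o_read.push_back(rd + 1);
      o_ref.push_back(p.ref + 1);
      o_start.push_back((double)(p.start + 1));
      o_strand.push_back(p.strand == 0 ? 1 : -1);
      o_score.push_back(p.score);
      o_qlen.push_back(p.qlen);
      o_cols.push_back(p.cols);
      o_match.push_back(p.matches);
    }
  }
  return DataFrame::create(
      _["read"] = o_read, _["ref"] = o_ref, _["start"] = o_start,
      _["strand"] = o_strand, _["score"] = o_score,
      _["aligned_read_bases"] = o_qlen, _["aligned_columns"] = o_cols,
      _["matches"] = o_match);
}

// ---------------------------------------------------------------------------
// Single-linkage clustering of 2-D points with per-axis linkage distance d:
// points are linked when |da| <= d AND |dt| <= d; returns component ids.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_single_linkage2d(NumericVector a, NumericVector t, double d) {
  const int n = a.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return a[x] < a[y]; });
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (a[ord[j]] - a[ord[i]] > d) break;
      if (std::abs(t[ord[j]] - t[ord[i]]) <= d) {
        int ri = find(ord[i]), rj = find(ord[j]);
        if (ri != rj) parent[ri] = rj;
      }
    }
  }
  IntegerVector out(n);
  std::unordered_map<int, int> relab;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relab.find(r);
    if (it == relab.end()) { relab[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}
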