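// Core engines: k-mer index, seed-and-extend read mapper with soft clips,
// banded gapped extension (single indel <= gap_cap), Smith-Waterman oracle,
// pileup, and the paired-end fragment simulator. All randomness goes through
// R's RNG so set.seed() gives byte-identical output.

#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const int SCORE_MATCH = 1;
static const int SCORE_MISMATCH = -4;
// gap of length l costs GAP_OPEN + l
static const int GAP_OPEN = 5;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(std::string(x[i]));
  out.names() = x.names();
  return out;
}

struct KIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::vector<uint64_t> offset;   // global start of each seq
  uint64_t total;
  std::vector<uint64_t> keys;     // sorted k-mer codes
  std::vector<uint64_t> posv;     // global positions, parallel to keys
};

static int seq_of(const KIndex& ix, uint64_t g) {
  // index of the sequence containing global position g
  int lo = 0, hi = (int)ix.offset.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (ix.offset[mid] <= g) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  KIndex* ix = new KIndex();
  ix->k = k;
  uint64_t tot = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    ix->seqs.push_back(std::string(seqs[i]));
    ix->names.push_back(std::string(names[i]));
    ix->offset.push_back(tot);
    tot += ix->seqs.back().size();
  }
  ix->total = tot;
  std::vector<std::pair<uint64_t, uint64_t>> kv;
  kv.reserve(tot);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t s = 0; s < ix->seqs.size(); ++s) {
    const std::string& sq = ix->seqs[s];
    if ((int)sq.size() < k) continue;
    uint64_t code = 0; int run = 0;
    for (size_t i = 0; i < sq.size(); ++i) {
      int b = base2code(sq[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        kv.push_back(std::make_pair(code, ix->offset[s] + i - k + 1));
    }
  }
  std::sort(kv.begin(), kv.end());
  ix->keys.reserve(kv.size());
  ix->posv.reserve(kv.size());
  for (auto& p : kv) { ix->keys.push_back(p.first); ix->posv.push_back(p.second); }
  XPtr<KIndex> xp(ix, true);
  return xp;
}

// [[Rcpp::export]]
double cpp_index_size(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return (double)xp->keys.size();
}

static inline std::pair<size_t, size_t> lookup(const KIndex& ix, uint64_t code) {
  auto lo = std::lower_bound(ix.keys.begin(), ix.keys.end(), code);
  auto hi = std::upper_bound(lo, ix.keys.end(), code);
  return std::make_pair((size_t)(lo - ix.keys.begin()), (size_t)(hi - ix.keys.begin()));
}

// Per-position multiplicity of the k-mer starting there; then a position is
// masked when every k-mer window inside the read-length window around it is
// multi-occurring (forward-strand occurrence counting).
// [[Rcpp::export]]
List cpp_kmer_mask(SEXP xp_, int window) {
  XPtr<KIndex> xp(xp_);
  const KIndex& ix = *xp;
  int k = ix.k;
  List out(ix.seqs.size());
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  for (size_t s = 0; s < ix.seqs.size(); ++s) {
    const std::string& sq = ix.seqs[s];
    int L = (int)sq.size();
    LogicalVector m(L, false);
    if (L >= k) {
      std::vector<int> multi(L - k + 1, 0);
      uint64_t code = 0; int run = 0;
      for (int i = 0; i < L; ++i) {
        int b = base2code(sq[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
          auto rg = lookup(ix, code);
          multi[i - k + 1] = (rg.second - rg.first) >= 2 ? 1 : 0;
        }
      }
      // prefix sums of unique (non-multi) k-mer starts
      int nk = L - k + 1;
      std::vector<int> cs(nk + 1, 0);
      for (int i = 0; i < nk; ++i) cs[i + 1] = cs[i] + (1 - multi[i]);
      int span = window - k + 1;   // k-mer starts covered by one window
      if (span < 1) span = 1;
      for (int i = 0; i < L; ++i) {
        int a = std::max(0, std::min(i, nk - 1));
        int b2 = std::min(nk - 1, i + span - 1);
        int a2 = std::min(a, b2);
        bool all_multi = (cs[b2 + 1] - cs[a2]) == 0;
        m[i] = all_multi;
      }
    }
    out[s] = m;
  }
  out.names() = wrap(ix.names);
  return out;
}

struct Aln {
  int ref;        // 0-based seq index, -1 unmapped
  long pos;       // 1-based leftmost aligned ref position
  int strand;     // +1 / -1
  std::string cigar;
  int score;
  int nm;
  int qstart, qend;  // 1-based aligned query range (oriented query)
};

// Ungapped extension at a fixed diagonal: best-scoring contiguous query
// segment (Kadane), clips free at both ends.
static Aln extend_ungapped(const KIndex& ix, const std::string& q,
                           int seq_id, long diag /*0-based ref pos of q[0]*/) {
  const std::string& ref = ix.seqs[seq_id];
  int n = (int)q.size();
  long L = (long)ref.size();
  Aln a; a.ref = -1; a.pos = 0; a.strand = 1; a.score = -1; a.nm = 0;
  int best = -1, bs = 0, be = -1;
  int cur = 0, cs = 0;
  for (int i = 0; i < n; ++i) {
    long rp = diag + i;
    int v;
    if (rp < 0 || rp >= L) v = -1000000;
    else v = (q[i] == ref[rp]) ? SCORE_MATCH : SCORE_MISMATCH;
    if (cur <= 0) { cur = v; cs = i; } else cur += v;
    if (cur > best) { best = cur; bs = cs; be = i; }
  }
  if (best <= 0 || be < bs) return a;
  int nm = 0;
  for (int i = bs; i <= be; ++i)
    if (q[i] != ref[diag + i]) ++nm;
  a.ref = seq_id;
  a.pos = diag + bs + 1;
  a.score = best;
  a.nm = nm;
  a.qstart = bs + 1; a.qend = be + 1;
  std::string cg;
  if (bs > 0) cg += std::to_string(bs) + "S";
  cg += std::to_string(be - bs + 1) + "M";
  if (be < n - 1) cg += std::to_string(n - 1 - be) + "S";
  a.cigar = cg;
  return a;
}

// Smith-Waterman with capped gap length (single-step gaps of length <= cap),
// free clips at query ends. Used for gapped extension and as the exhaustive
// oracle (ref window = whole sequence).
static Aln sw_core(const std::string& q, const std::string& ref,
                   long ref_off /*0-based offset of window in seq*/,
                   int gap_cap) {
  int n = (int)q.size(), m = (int)ref.size();
  Aln a; a.ref = -1; a.pos = 0; a.strand = 1; a.score = -1; a.nm = 0;
  if (n == 0 || m == 0) return a;
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<uint8_t> T((n + 1) * (m + 1), 0); // 0 stop, 1 diag, 2+l del(ref gap? ref consumed), 20+l ins
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (q[i - 1] == ref[j - 1]) ? SCORE_MATCH : SCORE_MISMATCH;
      int v = H[at(i - 1, j - 1)] + s;
      uint8_t t = 1;
      for (int l = 1; l <= gap_cap; ++l) {
        if (j - 1 - l >= 0) {  // deletion: skip l ref bases
          int w = H[at(i - 1, j - 1 - l)] + s - (GAP_OPEN + l);
          if (w > v) { v = w; t = (uint8_t)(2 + l); }
        }
        if (i - 1 - l >= 1) {  // insertion: skip l query bases
          int w = H[at(i - 1 - l, j - 1)] + s - (GAP_OPEN + l);
          if (w > v) { v = w; t = (uint8_t)(20 + l); }
        }
      }
      if (v <= 0) { v = 0; t = 0; }
      H[at(i, j)] = v; T[at(i, j)] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return a;
  // traceback
  std::vector<std::pair<char, int>> ops; // reversed
  int i = bi, j = bj, nm = 0;
  int qend = bi, qstart = bi, rend = bj, rstart = bj;
  while (i > 0 && j > 0 && T[at(i, j)] != 0) {
    uint8_t t = T[at(i, j)];
    if (q[i - 1] != ref[j - 1]) ++nm;
    if (t == 1) {
      ops.push_back(std::make_pair('M', 1));
      --i; --j;
    } else if (t >= 2 && t < 20) {
      int l = t - 2;
      ops.push_back(std::make_pair('M', 1));
      ops.push_back(std::make_pair('D', l));
      nm += l;
      i -= 1; j -= 1 + l;
    } else {
      int l = t - 20;
      ops.push_back(std::make_pair('M', 1));
      ops.push_back(std::make_pair('I', l));
      nm += l;
      i -= 1 + l; j -= 1;
    }
    qstart = i + 1; rstart = j + 1;
  }
  // compress ops
  std::string cg;
  if (qstart > 1) cg += std::to_string(qstart - 1) + "S";
  char pc = 0; int pl = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (it->first == pc) pl += it->second;
    else {
      if (pc) cg += std::to_string(pl) + pc;
      pc = it->first; pl = it->second;
    }
  }
  if (pc) cg += std::to_string(pl) + pc;
  if (qend < n) cg += std::to_string(n - qend) + "S";
  a.ref = 0;
  a.pos = ref_off + rstart;  // 1-based
  a.score = best;
  a.nm = nm;
  a.cigar = cg;
  a.qstart = qstart; a.qend = qend;
  (void)rend;
  return a;
}

// [[Rcpp::export]]
List cpp_sw(std::string query, std::string ref, int gap_cap = 6) {
  Aln a = sw_core(query, ref, 0, gap_cap);
  return List::create(_["score"] = a.score, _["pos"] = (double)a.pos,
                      _["cigar"] = a.cigar, _["nm"] = a.nm,
                      _["qstart"] = a.qstart, _["qend"] = a.qend);
}

struct Cand {
  int seq_id;
  long diag_min, diag_max; // 0-based ref pos of q[0]
  int votes;
  int strand;
};

static void collect_cands(const KIndex& ix, const std::string& q, int strand,
                          int occ_max, std::vector<Cand>& out) {
  int k = ix.k;
  int n = (int)q.size();
  if (n < k) return;
  const uint64_t kmask = (1ULL << (2 * k)) - 1;
  int stride = n >= 80 ? 3 : 1;
  std::vector<std::pair<long, int>> hits; // (global diag, qpos) per seed hit
  uint64_t code = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2code(q[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & kmask;
    ++run;
    int qpos = i - k + 1;
    if (run >= k && (qpos % stride) == 0) {
      auto rg = lookup(ix, code);
      size_t cnt = rg.second - rg.first;
      if (cnt == 0 || (int)cnt > occ_max) continue;
      for (size_t h = rg.first; h < rg.second; ++h)
        hits.push_back(std::make_pair((long)ix.posv[h] - qpos, qpos));
    }
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end());
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    long dmin = hits[i].first, dmax = hits[i].first;
    std::vector<int> qs;
    while (j < hits.size() && hits[j].first - dmax <= 6) {
      dmax = hits[j].first;
      qs.push_back(hits[j].second);
      ++j;
    }
    std::sort(qs.begin(), qs.end());
    qs.erase(std::unique(qs.begin(), qs.end()), qs.end());
    // clamp diag cluster to one sequence (use midpoint)
    long mid = (dmin + dmax) / 2;
    long probe = std::max(0L, std::min((long)ix.total - 1, mid + (long)ix.k));
    int sid = seq_of(ix, probe);
    Cand c;
    c.seq_id = sid;
    c.diag_min = dmin - (long)ix.offset[sid];
    c.diag_max = dmax - (long)ix.offset[sid];
    c.votes = (int)qs.size();
    c.strand = strand;
    out.push_back(c);
    i = j;
  }
}

static Aln eval_cand(const KIndex& ix, const std::string& qf, const std::string& qr,
                     const Cand& c, int gap_cap) {
  const std::string& q = (c.strand > 0) ? qf : qr;
  Aln a;
  if (c.diag_max == c.diag_min) {
    a = extend_ungapped(ix, q, c.seq_id, c.diag_min);
    // a clipped tail can hide an indel too short-sided to seed its own
    // diagonal: retry with the gapped aligner and keep any improvement
    int n = (int)q.size();
    if (a.ref >= 0 && (a.qstart > 3 || a.qend < n - 2)) {
      const std::string& ref = ix.seqs[c.seq_id];
      long w0 = std::max(0L, c.diag_min - gap_cap - 4);
      long w1 = std::min((long)ref.size(),
                         c.diag_min + (long)n + gap_cap + 4);
      if (w1 > w0) {
        Aln b = sw_core(q, ref.substr(w0, w1 - w0), w0, gap_cap);
        if (b.score > a.score) {
          b.ref = c.seq_id;
          b.strand = c.strand;
          a = b;
        }
      }
    }
  } else {
    const std::string& ref = ix.seqs[c.seq_id];
    long w0 = std::max(0L, c.diag_min - 2);
    long w1 = std::min((long)ref.size(), c.diag_max + (long)q.size() + 2);
    if (w1 <= w0) { a.ref = -1; a.score = -1; return a; }
    a = sw_core(q, ref.substr(w0, w1 - w0), w0, gap_cap);
    if (a.score > 0) a.ref = c.seq_id;
  }
  a.strand = c.strand;
  return a;
}

// Map a batch of reads. Returns one best record per read (ref_idx NA when
// unmapped), with mapping quality 60 for a unique best hit, 0 for ties,
// interpolated by score gap otherwise.
// [[Rcpp::export]]
DataFrame cpp_map_batch(SEXP xp_, CharacterVector reads, int occ_max = 16,
                        int max_cands = 6, int gap_cap = 6) {
  XPtr<KIndex> xp(xp_);
  const KIndex& ix = *xp;
  R_xlen_t N = reads.size();
  IntegerVector ref(N), score(N), nm(N), mq(N), ties(N), strand(N);
  NumericVector pos(N);
  CharacterVector cigar(N);
  for (R_xlen_t r = 0; r < N; ++r) {
    std::string qf = std::string(reads[r]);
    std::string qr = revcomp(qf);
    std::vector<Cand> cands;
    collect_cands(ix, qf, 1, occ_max, cands);
    collect_cands(ix, qr, -1, occ_max, cands);
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.votes > b.votes; });
    if ((int)cands.size() > max_cands) cands.resize(max_cands);
    std::vector<Aln> alns;
    for (auto& c : cands) {
      Aln a = eval_cand(ix, qf, qr, c, gap_cap);
      if (a.ref >= 0 && a.score > 0) alns.push_back(a);
    }
    if (alns.empty()) {
      ref[r] = NA_INTEGER; pos[r] = NA_REAL; strand[r] = NA_INTEGER;
      cigar[r] = NA_STRING; score[r] = NA_INTEGER; nm[r] = NA_INTEGER;
      mq[r] = 0; ties[r] = 0;
      continue;
    }
    // de-duplicate same-locus alignments, keep best
    std::sort(alns.begin(), alns.end(), [](const Aln& a, const Aln& b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.pos != b.pos) return a.pos < b.pos;
      return a.score > b.score;
    });
    std::vector<Aln> uniq;
    for (auto& a : alns) {
      bool dup = false;
      for (auto& u : uniq)
        if (u.ref == a.ref && std::labs(u.pos - a.pos) < 30) {
          dup = true;
          if (a.score > u.score) u = a;
          break;
        }
      if (!dup) uniq.push_back(a);
    }
    std::sort(uniq.begin(), uniq.end(), [](const Aln& a, const Aln& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.ref != b.ref) return a.ref < b.ref;
      return a.pos < b.pos;  // ties broken toward lowest coordinate
    });
    const Aln& b = uniq[0];
    // Only alignments explaining (largely) the same query bases compete
    // for mapping quality: the complementary segment of a split read maps
    // elsewhere by construction and must not penalise the primary.
    int n_read = (int)qf.size();
    auto raw_range = [n_read](const Aln& a) {
      if (a.strand > 0) return std::make_pair(a.qstart, a.qend);
      return std::make_pair(n_read - a.qend + 1, n_read - a.qstart + 1);
    };
    auto brr = raw_range(b);
    int s2 = -1000000, nt = 1;
    for (size_t u = 1; u < uniq.size(); ++u) {
      auto ur = raw_range(uniq[u]);
      int ov = std::min(brr.second, ur.second) -
               std::max(brr.first, ur.first) + 1;
      int minlen = std::min(brr.second - brr.first, ur.second - ur.first) + 1;
      if (ov < (minlen + 1) / 2) continue;  // complementary segment
      if (uniq[u].score > s2) s2 = uniq[u].score;
      if (uniq[u].score == b.score) ++nt;
    }
    int q;
    if (nt > 1) q = 0;
    else if (s2 <= -1000000) q = 60;
    else q = std::max(0, std::min(60, 3 * (b.score - s2)));
    ref[r] = b.ref + 1;
    pos[r] = (double)b.pos;
    strand[r] = b.strand;
    cigar[r] = b.cigar;
    score[r] = b.score;
    nm[r] = b.nm;
    mq[r] = q;
    ties[r] = nt;
  }
  return DataFrame::create(_["ref_idx"] = ref, _["pos"] = pos,
                           _["strand"] = strand, _["cigar"] = cigar,
                           _["score"] = score, _["nm"] = nm, _["mq"] = mq,
                           _["ties"] = ties, _["stringsAsFactors"] = false);
}

// All candidate alignments of one (short) query, best first. Used for
// realigning clipped sequences of split reads.
// [[Rcpp::export]]
DataFrame cpp_map_hits(SEXP xp_, std::string query, int occ_max = 24,
                       int max_cands = 12, int gap_cap = 6) {
  XPtr<KIndex> xp(xp_);
  const KIndex& ix = *xp;
  std::string qf = query, qr = revcomp(query);
  std::vector<Cand> cands;
  collect_cands(ix, qf, 1, occ_max, cands);
  collect_cands(ix, qr, -1, occ_max, cands);
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.votes > b.votes; });
  if ((int)cands.size() > max_cands) cands.resize(max_cands);
  std::vector<Aln> alns;
  for (auto& c : cands) {
    Aln a = eval_cand(ix, qf, qr, c, gap_cap);
    if (a.ref >= 0 && a.score > 0) alns.push_back(a);
  }
  std::vector<Aln> uniq;
  for (auto& a : alns) {
    bool dup = false;
    for (auto& u : uniq)
      if (u.ref == a.ref && u.strand == a.strand && std::labs(u.pos - a.pos) < 15) {
        dup = true;
        if (a.score > u.score) u = a;
        break;
      }
    if (!dup) uniq.push_back(a);
  }
  std::sort(uniq.begin(), uniq.end(), [](const Aln& a, const Aln& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ref != b.ref) return a.ref < b.ref;
    return a.pos < b.pos;
  });
  int n = (int)uniq.size();
  IntegerVector ref(n), score(n), nm(n), strand(n), qstart(n), qend(n);
  NumericVector pos(n);
  CharacterVector cigar(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = uniq[i].ref + 1; pos[i] = (double)uniq[i].pos;
    strand[i] = uniq[i].strand; cigar[i] = uniq[i].cigar;
    score[i] = uniq[i].score; nm[i] = uniq[i].nm;
    qstart[i] = uniq[i].qstart; qend[i] = uniq[i].qend;
  }
  return DataFrame::create(_["ref_idx"] = ref, _["pos"] = pos,
                           _["strand"] = strand, _["cigar"] = cigar,
                           _["score"] = score, _["nm"] = nm,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["stringsAsFactors"] = false);
}

struct CigOp { char op; int len; };

static std::vector<CigOp> parse_cigar(const std::string& cg) {
  std::vector<CigOp> ops;
  int l = 0;
  for (char c : cg) {
    if (c >= '0' && c <= '9') l = l * 10 + (c - '0');
    else { ops.push_back({c, l}); l = 0; }
  }
  return ops;
}

// Pileup over host sequences: per-position depth and A/C/G/T counts from
// aligned (oriented) read sequences, indel allele tally, and a per-position
// counter of reads excluded for construct linkage. Short soft clips
// (clip_support_min..clip_support_max bases) that exactly match the
// reference after skipping 1..clip_support_del bases are counted as
// split-read support for the corresponding short deletion (reads whose
// deletion-side tail was too short for a gapped alignment).
// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_seqs, IntegerVector ref_idx,
                NumericVector pos, CharacterVector cigar, CharacterVector seq,
                IntegerVector mq, LogicalVector excluded, int min_mq = 1,
                int clip_support_min = 2, int clip_support_max = 11,
                int clip_support_del = 8) {
  int nref = (int)ref_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = std::string(ref_seqs[i]);
  List depth_l(nref), counts_l(nref), excl_l(nref);
  std::vector<IntegerVector> depth(nref), excl(nref);
  std::vector<IntegerMatrix> cnt(nref);
  for (int i = 0; i < nref; ++i) {
    int L = (int)refs[i].size();
    depth[i] = IntegerVector(L, 0);
    excl[i] = IntegerVector(L, 0);
    cnt[i] = IntegerMatrix(4, L);
  }
  std::map<std::pair<int, long>, std::map<std::pair<std::string, std::string>, int>> indels;
  R_xlen_t N = ref_idx.size();
  for (R_xlen_t r = 0; r < N; ++r) {
    if (ref_idx[r] == NA_INTEGER) continue;
    int ri = ref_idx[r] - 1;
    if (ri < 0 || ri >= nref) continue;
    bool exc = excluded[r];
    if (!exc && mq[r] < min_mq) continue;
    std::string s = std::string(seq[r]);
    long rp = (long)pos[r] - 1;  // 0-based
    long qp = 0;
    const std::string& ref = refs[ri];
    long L = (long)ref.size();
    auto ops = parse_cigar(std::string(cigar[r]));
    auto clip_deletion = [&](long clip_q, int clip_len, bool leading) {
      // leading: clip precedes the alignment (deletion ends at rp);
      // trailing: clip follows it (deletion starts at rp)
      if (exc || clip_len < clip_support_min || clip_len > clip_support_max)
        return;
      for (int d = 1; d <= clip_support_del; ++d) {
        long rstart = leading ? rp - d - clip_len : rp + d;
        if (rstart < 0 || rstart + clip_len > L) continue;
        bool match = true;
        for (int i = 0; i < clip_len && match; ++i)
          if (s[clip_q + i] != ref[rstart + i]) match = false;
        if (match) {
          long anchor = leading ? rp - d - 1 : rp - 1;
          if (anchor >= 0 && anchor + d + 1 <= L) {
            std::string ra = ref.substr(anchor, d + 1);
            indels[{ri, anchor + 1}][{ra, ra.substr(0, 1)}] += 1;
          }
          break;
        }
      }
    };
    for (size_t oi = 0; oi < ops.size(); ++oi) {
      auto& o = ops[oi];
      if (o.op == 'S') {
        if (oi == 0) clip_deletion(qp, o.len, true);
        else if (oi == ops.size() - 1) clip_deletion(qp, o.len, false);
        qp += o.len;
        continue;
      }
      if (o.op == 'M') {
        for (int i = 0; i < o.len; ++i) {
          long p = rp + i;
          if (p < 0 || p >= L) continue;
          if (exc) { excl[ri][p] += 1; continue; }
          depth[ri][p] += 1;
          int b = base2code(s[qp + i]);
          if (b >= 0) cnt[ri](b, p) += 1;
        }
        rp += o.len; qp += o.len;
      } else if (o.op == 'D') {
        if (!exc) {
          long anchor = rp - 1;  // previous aligned ref base, 0-based
          if (anchor >= 0 && rp + o.len <= L) {
            std::string ra = ref.substr(anchor, o.len + 1);
            std::string aa = ra.substr(0, 1);
            indels[{ri, anchor + 1}][{ra, aa}] += 1;
            for (int i = 0; i < o.len; ++i) depth[ri][rp + i] += 1;
          }
        }
        rp += o.len;
      } else if (o.op == 'I') {
        if (!exc) {
          long anchor = rp - 1;
          if (anchor >= 0 && anchor < L) {
            std::string ra = ref.substr(anchor, 1);
            std::string aa = ra + s.substr(qp, o.len);
            indels[{ri, anchor + 1}][{ra, aa}] += 1;
          }
        }
        qp += o.len;
      }
    }
  }
  for (int i = 0; i < nref; ++i) {
    depth_l[i] = depth[i];
    counts_l[i] = cnt[i];
    excl_l[i] = excl[i];
  }
  int ni = 0;
  for (auto& kv : indels) ni += (int)kv.second.size();
  IntegerVector iri(ni), icount(ni);
  NumericVector ipos(ni);
  CharacterVector iref(ni), ialt(ni);
  int j = 0;
  for (auto& kv : indels)
    for (auto& al : kv.second) {
      iri[j] = kv.first.first + 1;
      ipos[j] = (double)kv.first.second;  // 1-based anchor
      iref[j] = al.first.first;
      ialt[j] = al.first.second;
      icount[j] = al.second;
      ++j;
    }
  DataFrame idf = DataFrame::create(_["ref_idx"] = iri, _["pos"] = ipos,
                                    _["ref"] = iref, _["alt"] = ialt,
                                    _["count"] = icount,
                                    _["stringsAsFactors"] = false);
  return List::create(_["depth"] = depth_l, _["counts"] = counts_l,
                      _["excluded"] = excl_l, _["indels"] = idf);
}

// Per-cigar bookkeeping: reference bases consumed, query bases consumed,
// and soft-clip lengths at either end.
// [[Rcpp::export]]
DataFrame cpp_cigar_stats(CharacterVector cigar) {
  R_xlen_t n = cigar.size();
  IntegerVector ref_len(n), q_len(n), clip_l(n), clip_r(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (cigar[i] == NA_STRING) {
      ref_len[i] = NA_INTEGER; q_len[i] = NA_INTEGER;
      clip_l[i] = NA_INTEGER; clip_r[i] = NA_INTEGER;
      continue;
    }
    auto ops = parse_cigar(std::string(cigar[i]));
    int rl = 0, ql = 0, cl = 0, cr = 0;
    for (size_t j = 0; j < ops.size(); ++j) {
      char op = ops[j].op; int l = ops[j].len;
      if (op == 'M') { rl += l; ql += l; }
      else if (op == 'D') rl += l;
      else if (op == 'I') ql += l;
      else if (op == 'S') {
        ql += l;
        if (j == 0) cl = l; else cr = l;
      }
    }
    ref_len[i] = rl; q_len[i] = ql; clip_l[i] = cl; clip_r[i] = cr;
  }
  return DataFrame::create(_["ref_len"] = ref_len, _["q_len"] = q_len,
                           _["clip_left"] = clip_l, _["clip_right"] = clip_r);
}

// Paired-end fragment simulator over a set of haplotype sequences.
// Fragment lengths ~ Normal(frag_mean, frag_sd) truncated at [2*read_len, ..].
// Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
List cpp_sim_frags(CharacterVector seqs, int n_pairs, int read_len,
                   double frag_mean, double frag_sd, double err) {
  int ns = (int)seqs.size();
  std::vector<std::string> sv(ns);
  std::vector<double> cum(ns + 1, 0.0);
  for (int i = 0; i < ns; ++i) {
    sv[i] = std::string(seqs[i]);
    double w = ((int)sv[i].size() >= 2 * read_len) ? (double)sv[i].size() : 0.0;
    cum[i + 1] = cum[i] + w;
  }
  if (cum[ns] <= 0) stop("no sequence long enough for the fragment model");
  IntegerVector seq_idx(n_pairs), fstart(n_pairs), fend(n_pairs);
  CharacterVector r1(n_pairs), r2(n_pairs);
  const char* bases = "ACGT";
  for (int i = 0; i < n_pairs; ++i) {
    double u = R::runif(0.0, cum[ns]);
    int s = 0;
    while (s < ns - 1 && cum[s + 1] <= u) ++s;
    long L = (long)sv[s].size();
    long fl = (long)std::lround(R::rnorm(frag_mean, frag_sd));
    if (fl < 2L * read_len) fl = 2L * read_len;
    if (fl > L) fl = L;
    long start = 1 + (long)std::floor(R::unif_rand() * (double)(L - fl + 1));
    if (start < 1) start = 1;
    if (start + fl - 1 > L) start = L - fl + 1;
    std::string a = sv[s].substr(start - 1, read_len);
    std::string b = revcomp(sv[s].substr(start + fl - read_len - 1, read_len));
    if (err > 0) {
      for (std::string* rd : {&a, &b}) {
        int ne = (int)R::rbinom((double)read_len, err);
        for (int e = 0; e < ne; ++e) {
          int p = (int)std::floor(R::unif_rand() * read_len);
          if (p >= read_len) p = read_len - 1;
          char cur = (*rd)[p];
          char nb = cur;
          while (nb == cur) nb = bases[(int)std::floor(R::unif_rand() * 4.0)];
          (*rd)[p] = nb;
        }
      }
    }
    seq_idx[i] = s + 1;
    fstart[i] = (int)start;
    fend[i] = (int)(start + fl - 1);
    r1[i] = a;
    r2[i] = b;
  }
  return List::create(_["seq_idx"] = seq_idx, _["start"] = fstart,
                      _["end"] = fend, _["r1"] = r1, _["r2"] = r2);
}
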