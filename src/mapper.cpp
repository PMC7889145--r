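// Seed-and-extend ungapped read mapper with split-read support.
// The index holds two k-mer hash tables: full-length seeds (k, default 21)
// and shorter seeds (ksplit, default 15) used only when hunting breakpoint
// partitions, so that a 20 bp minimum segment can still anchor a seed.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static inline char compBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

struct KIndex {
  int k;
  int ksplit;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t> > tab;   // k-mers
  std::unordered_map<uint64_t, std::vector<uint64_t> > tabs;  // ksplit-mers
};

static inline uint64_t packHit(int chrom, int pos0) {
  return (static_cast<uint64_t>(chrom) << 32) | static_cast<uint32_t>(pos0);
}

static void addKmers(std::unordered_map<uint64_t, std::vector<uint64_t> >& tab,
                     const std::string& s, int chrom, int k) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0;  // valid bases accumulated
  for (size_t i = 0; i < s.size(); ++i) {
    int code = baseCode(s[i]);
    if (code < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | static_cast<uint64_t>(code)) & mask;
    if (++run >= k) tab[val].push_back(packHit(chrom, static_cast<int>(i) - k + 1));
  }
}

// returns false if the window contains a non-ACGT base
static bool encodeKmer(const std::string& s, int start, int k, uint64_t& out) {
  uint64_t val = 0;
  for (int i = 0; i < k; ++i) {
    int code = baseCode(s[start + i]);
    if (code < 0) return false;
    val = (val << 2) | static_cast<uint64_t>(code);
  }
  out = val;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector names, CharacterVector seqs, int k, int ksplit) {
  if (k < 1 || k > 31 || ksplit < 1 || ksplit > 31)
    stop("k and ksplit must be in [1, 31]");
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->ksplit = ksplit;
  for (int i = 0; i < names.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
    addKmers(idx->tab, idx->seqs.back(), i, k);
    addKmers(idx->tabs, idx->seqs.back(), i, ksplit);
  }
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerMatrix cpp_index_query(SEXP xp, std::string kmer) {
  XPtr<KIndex> idx(xp);
  IntegerMatrix empty(0, 2);
  if (static_cast<int>(kmer.size()) != idx->k) stop("query length must equal index k");
  uint64_t key;
  if (!encodeKmer(kmer, 0, idx->k, key)) return empty;
  std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it = idx->tab.find(key);
  if (it == idx->tab.end()) return empty;
  const std::vector<uint64_t>& hits = it->second;
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = static_cast<int>(hits[i] >> 32) + 1;           // chrom index, 1-based
    out(i, 1) = static_cast<int>(hits[i] & 0xffffffffULL) + 1; // position, 1-based
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_index_seqnames(SEXP xp) {
  XPtr<KIndex> idx(xp);
  return wrap(idx->names);
}

static std::string revComp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

struct Cand { int strand; int chrom; long anchor; int hits; };
static bool candLess(const Cand& a, const Cand& b) {
  if (a.strand != b.strand) return a.strand < b.strand;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  return a.anchor < b.anchor;
}
static bool candRank(const Cand& a, const Cand& b) {
  if (a.hits != b.hits) return a.hits > b.hits;
  return candLess(a, b);
}

struct MapResult {
  int status;        // 0 unique, 1 ambiguous, 2 unmapped
  int chrom, pos, nm;
  int strand;        // 0 '+', 1 '-'
  bool split;
  int b;
  int chrom2, pos2, strand2;
  int jc1, jp1, jc2, jp2;
  int jo1, jo2;      // 0 '+', 1 '-'
  MapResult() : status(2), chrom(0), pos(0), nm(0), strand(0), split(false), b(0),
                chrom2(0), pos2(0), strand2(0), jc1(0), jp1(0), jc2(0), jp2(0),
                jo1(0), jo2(0) {}
};

static void lookupSeeds(const std::unordered_map<uint64_t, std::vector<uint64_t> >& tab,
                        const std::string& seq, int off, int k,
                        std::vector<uint64_t>& hitsOut) {
  uint64_t key;
  if (!encodeKmer(seq, off, k, key)) return;
  std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it = tab.find(key);
  if (it == tab.end()) return;
  hitsOut.insert(hitsOut.end(), it->second.begin(), it->second.end());
}

// Full-length ungapped placement: best (fewest-mismatch) start over candidate
// diagonals seeded at stride k on both strands.
static void mapFull(const KIndex& idx, const std::string& read, const std::string& rc,
                    int mmMax, MapResult& res) {
  const int L = static_cast<int>(read.size());
  const int k = idx.k;
  std::vector<Cand> cands;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = (strand == 0) ? read : rc;
    std::vector<int> offs;
    for (int o = 0; o + k <= L; o += k) offs.push_back(o);
    if (offs.empty() || offs.back() != L - k) offs.push_back(L - k);
    for (size_t oi = 0; oi < offs.size(); ++oi) {
      std::vector<uint64_t> hits;
      lookupSeeds(idx.tab, q, offs[oi], k, hits);
      for (size_t h = 0; h < hits.size(); ++h) {
        Cand c;
        c.strand = strand;
        c.chrom = static_cast<int>(hits[h] >> 32);
        c.anchor = static_cast<long>(hits[h] & 0xffffffffULL) - offs[oi];
        c.hits = 1;
        cands.push_back(c);
      }
    }
  }
  std::sort(cands.begin(), cands.end(), candLess);
  cands.erase(std::unique(cands.begin(), cands.end(),
                          [](const Cand& a, const Cand& b) {
                            return a.strand == b.strand && a.chrom == b.chrom && a.anchor == b.anchor;
                          }),
              cands.end());
  int bestMm = mmMax + 1, nBest = 0;
  Cand best;
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    const Cand& c = cands[ci];
    const std::string& ref = idx.seqs[c.chrom];
    if (c.anchor < 0 || c.anchor + L > static_cast<long>(ref.size())) continue;
    const std::string& q = (c.strand == 0) ? read : rc;
    int mm = 0;
    for (int i = 0; i < L && mm <= bestMm; ++i)
      if (q[i] != ref[c.anchor + i]) ++mm;
    if (mm < bestMm) { bestMm = mm; best = c; nBest = 1; }
    else if (mm == bestMm) ++nBest;
  }
  if (bestMm <= mmMax && nBest >= 1) {
    res.status = (nBest == 1) ? 0 : 1;
    res.chrom = best.chrom + 1;
    res.pos = static_cast<int>(best.anchor) + 1;
    res.strand = best.strand;
    res.nm = bestMm;
  }
}

// Split placement: maximize matched bases over a breakpoint b in
// [minSeg, L - minSeg] with prefix and suffix mapped independently
// (possibly different chromosomes / strands). Ties on b take the
// smallest b; ties across diagonal pairs with differing junctions
// make the read ambiguous.
static void mapSplit(const KIndex& idx, const std::string& read, const std::string& rc,
                     double maxMmFrac, int minSeg, MapResult& res) {
  const int L = static_cast<int>(read.size());
  const int k2 = idx.ksplit;
  if (L < 2 * minSeg || L < k2) return;
  std::vector<Cand> cands;
  const int stride = 5;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = (strand == 0) ? read : rc;
    std::vector<int> offs;
    for (int o = 0; o + k2 <= L; o += stride) offs.push_back(o);
    if (offs.empty() || offs.back() != L - k2) offs.push_back(L - k2);
    for (size_t oi = 0; oi < offs.size(); ++oi) {
      std::vector<uint64_t> hits;
      lookupSeeds(idx.tabs, q, offs[oi], k2, hits);
      if (hits.size() > 50) continue;  // repetitive seed, uninformative
      for (size_t h = 0; h < hits.size(); ++h) {
        int chrom = static_cast<int>(hits[h] >> 32);
        long p = static_cast<long>(hits[h] & 0xffffffffULL);
        Cand c;
        c.strand = strand;
        c.chrom = chrom;
        // anchor A: 0-based ref position of read[0];  '+': ref[A+i], '-': comp(ref[A-i])
        c.anchor = (strand == 0) ? (p - offs[oi]) : (p + (L - 1) - offs[oi]);
        c.hits = 1;
        cands.push_back(c);
      }
    }
  }
  if (cands.empty()) return;
  std::sort(cands.begin(), cands.end(), candLess);
  // merge duplicates, accumulating seed-hit counts
  std::vector<Cand> uniq;
  for (size_t i = 0; i < cands.size(); ++i) {
    if (!uniq.empty() && uniq.back().strand == cands[i].strand &&
        uniq.back().chrom == cands[i].chrom && uniq.back().anchor == cands[i].anchor)
      uniq.back().hits += 1;
    else uniq.push_back(cands[i]);
  }
  if (uniq.size() > 24) {
    std::sort(uniq.begin(), uniq.end(), candRank);
    uniq.resize(24);
    std::sort(uniq.begin(), uniq.end(), candLess);
  }
  const int nC = static_cast<int>(uniq.size());
  const int mmMaxTotal = static_cast<int>(maxMmFrac * L);
  // cumulative mismatch / out-of-bounds arrays per candidate, in read coords
  std::vector<std::vector<int> > cumMm(nC), cumOob(nC);
  for (int ci = 0; ci < nC; ++ci) {
    const Cand& c = uniq[ci];
    const std::string& ref = idx.seqs[c.chrom];
    const long refLen = static_cast<long>(ref.size());
    cumMm[ci].assign(L + 1, 0);
    cumOob[ci].assign(L + 1, 0);
    for (int i = 0; i < L; ++i) {
      long rp = (c.strand == 0) ? (c.anchor + i) : (c.anchor - i);
      int mm = 1, oob = 1;
      if (rp >= 0 && rp < refLen) {
        oob = 0;
        char rb = (c.strand == 0) ? ref[rp] : compBase(ref[rp]);
        mm = (read[i] != rb) ? 1 : 0;
        if (c.strand == 1) mm = (rc[L - 1 - i] != ref[rp]) ? 1 : 0;  // equivalent, explicit
      }
      cumMm[ci][i + 1] = cumMm[ci][i] + mm;
      cumOob[ci][i + 1] = cumOob[ci][i] + oob;
    }
  }
  int bestScore = -1;
  bool tie = false;
  int bi = -1, bj = -1, bb = -1;
  int bjTuple[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 0; i < nC; ++i) {
    for (int j = 0; j < nC; ++j) {
      if (i == j) continue;
      const std::vector<int>& mmL = cumMm[i];
      const std::vector<int>& mmR = cumMm[j];
      const int mmRtot = mmR[L];
      for (int b = minSeg; b <= L - minSeg; ++b) {
        if (cumOob[i][b] != 0) continue;
        if (cumOob[j][L] - cumOob[j][b] != 0) continue;
        int left = mmL[b], right = mmRtot - mmR[b];
        if (left + right > mmMaxTotal) continue;
        if (left > maxMmFrac * b || right > maxMmFrac * (L - b)) continue;
        int score = L - left - right;
        if (score > bestScore) {
          bestScore = score; bi = i; bj = j; bb = b; tie = false;
        } else if (score == bestScore && !(i == bi && j == bj)) {
          // different diagonal pair achieving the same score: junction differs?
          tie = true;
        }
      }
    }
  }
  if (bestScore < 0 || bestScore < L - mmMaxTotal) return;
  const Cand& c1 = uniq[bi];
  const Cand& c2 = uniq[bj];
  const int b = bb;
  // junction sides: left segment contributes its junction-abutting end
  int jc1 = c1.chrom + 1, jc2 = c2.chrom + 1;
  int jp1, jo1, jp2, jo2;
  if (c1.strand == 0) { jp1 = static_cast<int>(c1.anchor) + b - 1 + 1; jo1 = 1; }  // '-'
  else { jp1 = static_cast<int>(c1.anchor) - (b - 1) + 1; jo1 = 0; }               // '+'
  if (c2.strand == 0) { jp2 = static_cast<int>(c2.anchor) + b + 1; jo2 = 0; }      // '+'
  else { jp2 = static_cast<int>(c2.anchor) - b + 1; jo2 = 1; }                     // '-'
  bjTuple[0] = jc1; bjTuple[1] = jp1; bjTuple[2] = jo1;
  bjTuple[3] = jc2; bjTuple[4] = jp2; bjTuple[5] = jo2;
  (void)bjTuple;
  if (tie) { res.status = 1; return; }
  res.status = 0;
  res.split = true;
  res.b = b;
  res.nm = L - bestScore;
  res.chrom = c1.chrom + 1;
  res.strand = c1.strand;
  res.pos = (c1.strand == 0) ? static_cast<int>(c1.anchor) + 1
                             : static_cast<int>(c1.anchor) - (b - 1) + 1;
  res.chrom2 = c2.chrom + 1;
  res.strand2 = c2.strand;
  res.pos2 = (c2.strand == 0) ? static_cast<int>(c2.anchor) + b + 1
                              : static_cast<int>(c2.anchor) - (L - 1) + 1;
  res.jc1 = jc1; res.jp1 = jp1; res.jo1 = jo1;
  res.jc2 = jc2; res.jp2 = jp2; res.jo2 = jo2;
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, double maxMmFrac,
                   int minSegment, bool trySplit) {
  XPtr<KIndex> idx(xp);
  const int n = reads.size();
  IntegerVector chrom(n), pos(n), nm(n), b(n), chrom2(n), pos2(n);
  IntegerVector jc1(n), jp1(n), jc2(n), jp2(n);
  CharacterVector strand(n), status(n), strand2(n), jo1(n), jo2(n);
  LogicalVector split(n);
  const char* orient[2] = {"+", "-"};
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    MapResult res;
    if (static_cast<int>(read.size()) >= idx->k) {
      std::string rc = revComp(read);
      int mmMax = static_cast<int>(maxMmFrac * read.size());
      mapFull(*idx, read, rc, mmMax, res);
      if (res.status == 2 && trySplit) mapSplit(*idx, read, rc, maxMmFrac, minSegment, res);
    }
    status[r] = (res.status == 0) ? "unique" : (res.status == 1 ? "ambiguous" : "unmapped");
    split[r] = res.split;
    if (res.status == 0) {
      chrom[r] = res.chrom; pos[r] = res.pos; nm[r] = res.nm;
      strand[r] = orient[res.strand];
    } else {
      chrom[r] = NA_INTEGER; pos[r] = NA_INTEGER; nm[r] = NA_INTEGER;
      strand[r] = NA_STRING;
    }
    if (res.split) {
      b[r] = res.b; chrom2[r] = res.chrom2; pos2[r] = res.pos2;
      strand2[r] = orient[res.strand2];
      jc1[r] = res.jc1; jp1[r] = res.jp1; jo1[r] = orient[res.jo1];
      jc2[r] = res.jc2; jp2[r] = res.jp2; jo2[r] = orient[res.jo2];
    } else {
      b[r] = NA_INTEGER; chrom2[r] = NA_INTEGER; pos2[r] = NA_INTEGER;
      strand2[r] = NA_STRING;
      jc1[r] = NA_INTEGER; jp1[r] = NA_INTEGER; jo1[r] = NA_STRING;
      jc2[r] = NA_INTEGER; jp2[r] = NA_INTEGER; jo2[r] = NA_STRING;
    }
  }
  return List::create(
    _["chrom"] = chrom, _["pos"] = pos, _["strand"] = strand, _["nm"] = nm,
    _["status"] = status, _["split"] = split, _["b"] = b,
    _["chrom2"] = chrom2, _["pos2"] = pos2, _["strand2"] = strand2,
    _["jchrom1"] = jc1, _["jpos1"] = jp1, _["jorient1"] = jo1,
    _["jchrom2"] = jc2, _["jpos2"] = jp2, _["jorient2"] = jo2);
}

// iid substitution errors; replacement drawn uniformly from the three
// other bases. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
  const char* bases = "ACGT";
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        int code = baseCode(s[j]);
        if (code < 0) continue;
        int shift = 1 + static_cast<int>(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = bases[(code + shift) & 3];
      }
    }
    out[i] = s;
  }
  return out;
}
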