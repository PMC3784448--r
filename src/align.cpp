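// Seed-and-extend micro-aligner core: 2-bit k-mer index over the forward
// strand of one reference, ungapped extension of seed candidates from both
// read strands. Exposed to R through thin wrappers in R/microalign.R.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

const int BAD_BASE = -1;

inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return BAD_BASE;
  }
}

inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement(s[i]);
  return out;
}

struct SeedIndex {
  std::string genome;
  int k;
  std::unordered_map<uint64_t, std::vector<int> > map;
};

// Encode genome[pos .. pos+k-1]; returns false if a non-ACGT base occurs.
bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(s[pos + i]);
    if (b == BAD_BASE) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

struct Candidate {
  int pos;      // 0-based genome start of the read placement
  int strand;   // 0 = '+', 1 = '-'
};

struct HitResult {
  bool aligned;
  int pos;          // 0-based
  int strand;       // 0/1
  int mismatches;
  int mapq;         // 0..60
};

int count_mismatches(const std::string& genome, int gpos,
                     const std::string& read, int cap) {
  int mm = 0;
  const size_t n = read.size();
  for (size_t i = 0; i < n; ++i) {
    if (genome[gpos + i] != read[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

HitResult align_one(const SeedIndex& idx, const std::string& fwd,
                    int max_mismatch) {
  HitResult res;
  res.aligned = false;
  const int k = idx.k;
  const int glen = (int)idx.genome.size();
  const int rlen = (int)fwd.size();
  if (rlen < k) return res;

  std::string strands[2];
  strands[0] = fwd;
  strands[1] = revcomp(fwd);

  std::vector<Candidate> cands;
  // seen placements per strand, linear scan (candidate counts are tiny)
  std::vector<int> seen[2];

  for (int st = 0; st < 2; ++st) {
    const std::string& seq = strands[st];
    // non-overlapping seeds plus one flush with the 3' end
    std::vector<int> offsets;
    for (int off = 0; off + k <= rlen; off += k) offsets.push_back(off);
    if (offsets.empty() || offsets.back() != rlen - k)
      offsets.push_back(rlen - k);
    for (size_t oi = 0; oi < offsets.size(); ++oi) {
      int off = offsets[oi];
      uint64_t code;
      if (!encode_kmer(seq, off, k, code)) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        idx.map.find(code);
      if (it == idx.map.end()) continue;
      const std::vector<int>& hits = it->second;
      for (size_t h = 0; h < hits.size(); ++h) {
        int start = hits[h] - off;
        if (start < 0 || start + rlen > glen) continue;
        bool dup = false;
        for (size_t s = 0; s < seen[st].size(); ++s)
          if (seen[st][s] == start) { dup = true; break; }
        if (dup) continue;
        seen[st].push_back(start);
        Candidate c; c.pos = start; c.strand = st;
        cands.push_back(c);
      }
    }
  }
  if (cands.empty()) return res;

  // Evaluate candidates; track best and second-best mismatch counts.
  // Counting is capped: anything beyond max_mismatch + 7 cannot change the
  // alignment outcome or the MAPQ-like score (10 * gap, ceiling 60).
  const int cap = max_mismatch + 7;
  int best = cap + 1, second = cap + 1;
  int best_pos = -1, best_strand = 0, n_best = 0;
  for (size_t i = 0; i < cands.size(); ++i) {
    int mm = count_mismatches(idx.genome, cands[i].pos, strands[cands[i].strand], cap);
    if (mm < best) {
      second = best;
      best = mm;
      best_pos = cands[i].pos;
      best_strand = cands[i].strand;
      n_best = 1;
    } else if (mm == best) {
      ++n_best;
      second = best;
      // deterministic tie-break: lowest coordinate, then forward strand
      if (cands[i].pos < best_pos ||
          (cands[i].pos == best_pos && cands[i].strand < best_strand)) {
        best_pos = cands[i].pos;
        best_strand = cands[i].strand;
      }
    } else if (mm < second) {
      second = mm;
    }
  }

  if (best > max_mismatch) return res;
  res.aligned = true;
  res.pos = best_pos;
  res.strand = best_strand;
  res.mismatches = best;
  if (n_best > 1) {
    res.mapq = 0;
  } else if (second > cap) {
    res.mapq = 60;  // no competing placement seen
  } else {
    int q = 10 * (second - best);
    res.mapq = q > 60 ? 60 : q;
  }
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".xp_index_build")]]
SEXP xp_index_build(std::string genome, int k) {
  if (k < 1) stop("k must be >= 1");
  if (k > 31) stop("k must be <= 31 (2-bit packed seeds)");
  if ((int)genome.size() < k) stop("genome shorter than k");
  XPtr<SeedIndex> ptr(new SeedIndex(), true);
  ptr->genome = genome;
  ptr->k = k;
  const int n = (int)genome.size() - k + 1;
  for (int pos = 0; pos < n; ++pos) {
    uint64_t code;
    if (!encode_kmer(genome, pos, k, code)) continue;
    ptr->map[code].push_back(pos);
  }
  return ptr;
}

// [[Rcpp::export(name = ".xp_index_lookup")]]
IntegerVector xp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> ptr(xp);
  if ((int)kmer.size() != ptr->k) stop("kmer length does not match index k");
  uint64_t code;
  if (!encode_kmer(kmer, 0, ptr->k, code)) return IntegerVector(0);
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
    ptr->map.find(code);
  if (it == ptr->map.end()) return IntegerVector(0);
  return wrap(it->second);  // 0-based
}

// [[Rcpp::export(name = ".xp_align_batch")]]
List xp_align_batch(SEXP xp, CharacterVector seqs, int max_mismatch) {
  XPtr<SeedIndex> ptr(xp);
  const int n = seqs.size();
  IntegerVector pos(n), mism(n), mapq(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    HitResult h = align_one(*ptr, s, max_mismatch);
    if (!h.aligned) {
      pos[i] = NA_INTEGER; mism[i] = NA_INTEGER; mapq[i] = NA_INTEGER;
      strand[i] = NA_STRING;
    } else {
      pos[i] = h.pos + 1;  // 1-based for R
      mism[i] = h.mismatches;
      mapq[i] = h.mapq;
      strand[i] = h.strand == 0 ? "+" : "-";
    }
  }
  return List::create(_["position"] = pos, _["strand"] = strand,
                      _["mismatches"] = mism, _["mapq_like"] = mapq);
}

// [[Rcpp::export(name = ".xp_revcomp")]]
CharacterVector xp_revcomp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
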