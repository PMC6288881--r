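#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// Exact k-mer seed index over one converted genome (a set of sequences that
// share a conversion tag).  k-mers are 2-bit packed, so k is capped at 31;
// k-mers touching an 'N' (or any non-ACGT byte) are never indexed.
struct SeedIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> table;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// Encode seq[pos, pos+k) or return false if a non-ACGT byte intervenes.
static bool encode_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_seed_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s)
    idx->seqs.push_back(as<std::string>(seqs[s]));

  const uint64_t mask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  for (size_t s = 0; s < idx->seqs.size(); ++s) {
    const std::string& seq = idx->seqs[s];
    if ((int64_t)seq.size() < k) continue;
    // rolling encode; n_valid counts consecutive ACGT bases ending at i
    uint64_t v = 0;
    int n_valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int c = base_code(seq[i]);
      if (c < 0) {
        n_valid = 0;
        v = 0;
        continue;
      }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++n_valid >= k) {
        int32_t pos = (int32_t)(i - k + 1);
        idx->table[v].emplace_back((int32_t)s, pos);
      }
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_seed_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal index k");
  uint64_t v;
  if (!encode_kmer(kmer, 0, idx->k, v))
    return List::create(_["seq"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  auto it = idx->table.find(v);
  if (it == idx->table.end())
    return List::create(_["seq"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  const auto& hits = it->second;
  IntegerVector si(hits.size()), pp(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    si[i] = hits[i].first + 1;  // 1-based sequence index for R
    pp[i] = hits[i].second;     // 0-based position
  }
  return List::create(_["seq"] = si, _["pos"] = pp);
}

// [[Rcpp::export]]
int cpp_seed_index_k(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return idx->k;
}

// [[Rcpp::export]]
int cpp_seed_index_nkmers(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  return (int)idx->table.size();
}

// Ungapped end-to-end alignment of converted reads against the indexed
// converted genome.  Candidate placements come from exact seed matches at
// read offsets 0, k, 2k, ...; each candidate is verified by full-length
// Hamming comparison with early abort past max_mm.  Placements are
// deduplicated on (sequence, position).  Any 0-mismatch placement is always
// found; placements with more than floor(len/k) - 1 mismatches may be missed
// (pigeonhole bound).
// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector reads, SEXP xp, int max_mm) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  if (max_mm < 0) stop("max_mm must be >= 0");

  std::vector<int> out_read, out_seq, out_pos, out_mm;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* cr = CHAR(STRING_ELT(reads, r));
    std::string read(cr);
    const int len = (int)read.size();
    if (len < k) continue;  // caller accounts for skipped reads

    std::unordered_set<uint64_t> seen;  // (seq << 32) | pos candidates tried
    for (int off = 0; off + k <= len; off += k) {
      uint64_t v;
      if (!encode_kmer(read, off, k, v)) continue;
      auto it = idx->table.find(v);
      if (it == idx->table.end()) continue;
      for (const auto& hit : it->second) {
        const int32_t si = hit.first;
        const int64_t cand = (int64_t)hit.second - off;
        const std::string& seq = idx->seqs[si];
        if (cand < 0 || cand + len > (int64_t)seq.size()) continue;
        uint64_t key = ((uint64_t)si << 32) | (uint64_t)cand;
        if (!seen.insert(key).second) continue;
        int mm = 0;
        const char* g = seq.data() + cand;
        for (int i = 0; i < len; ++i) {
          if (g[i] != read[i] && ++mm > max_mm) break;
        }
        if (mm <= max_mm) {
          out_read.push_back((int)r + 1);
          out_seq.push_back(si + 1);
          out_pos.push_back((int)cand);
          out_mm.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["seq"] = out_seq,
                           _["pos"] = out_pos, _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// FNV-1a 64-bit over the key bytes: deterministic across runs, platforms and
// process boundaries (stands in for a data-parallel framework's portable
// per-key hash).
static inline uint64_t fnv1a64(const char* s, size_t n) {
  uint64_t h = 14695981039346656037ULL;  // offset basis
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;  // FNV prime
  }
  return h;
}

// [[Rcpp::export]]
CharacterVector cpp_fnv1a64_hex(CharacterVector keys) {
  CharacterVector out(keys.size());
  char buf[17];
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    const char* s = CHAR(STRING_ELT(keys, i));
    uint64_t h = fnv1a64(s, strlen(s));
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_fnv1a64_mod(CharacterVector keys, int n) {
  if (n < 1) stop("n must be >= 1");
  IntegerVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    const char* s = CHAR(STRING_ELT(keys, i));
    uint64_t h = fnv1a64(s, strlen(s));
    out[i] = (int)(h % (uint64_t)n) + 1;  // 1-based partition id
  }
  return out;
}
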