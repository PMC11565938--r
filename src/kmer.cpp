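#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 64-bit MurmurHash3-style string hash (FNV-1a accumulation followed by the
// murmur3 fmix64 finalizer, seed xored in). Values are truncated to 53 bits
// so they round-trip exactly through R doubles.
static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t hash_bytes(const char *s, size_t n, uint64_t seed) {
  uint64_t h = 1469598103934665603ULL ^ seed;
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return fmix64(h) & ((1ULL << 53) - 1);
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

//' @noRd
// [[Rcpp::export(name = ".hash_kmers")]]
NumericVector hash_kmers_cpp(CharacterVector kmers, double seed) {
  uint64_t sd = (uint64_t)seed;
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    out[i] = (double)hash_bytes(s, strlen(s), sd);
  }
  return out;
}

// Count canonical k-mers (lexicographic min of the k-mer and its reverse
// complement) over every length-k window of every read; windows containing
// a non-ACGT symbol are skipped. Lowercase input is uppercased.
//' @noRd
// [[Rcpp::export(name = ".count_canonical_kmers")]]
DataFrame count_canonical_kmers_cpp(CharacterVector reads, int k) {
  if (k < 1) stop("k must be >= 1");
  std::unordered_map<std::string, int> counts;
  std::string fwd, rev;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string seq(CHAR(STRING_ELT(reads, r)));
    for (auto &c : seq) c = (char)toupper((unsigned char)c);
    if ((int)seq.size() < k) continue;
    for (size_t i = 0; i + k <= seq.size(); ++i) {
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        if (!valid_base(seq[i + j])) { ok = false; break; }
      }
      if (!ok) continue;
      fwd.assign(seq, i, k);
      rev.resize(k);
      for (int j = 0; j < k; ++j) rev[j] = comp(fwd[k - 1 - j]);
      const std::string &canon = (rev < fwd) ? rev : fwd;
      ++counts[canon];
    }
  }
  CharacterVector kmers(counts.size());
  IntegerVector cnt(counts.size());
  R_xlen_t i = 0;
  for (auto &kv : counts) {
    kmers[i] = kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["kmer"] = kmers, _["count"] = cnt,
                           _["stringsAsFactors"] = false);
}
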