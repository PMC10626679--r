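#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Complement of an upper-case base; 0 signals a non-ACGT character.
static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;
  }
}

// Canonical form: lexicographic min of a window and its reverse complement.
// Returns false if the window holds a non-ACGT character.
static bool canonical_window(const char* s, int k, std::string& out) {
  out.assign(s, k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) {
    char c = comp_base(s[i]);
    if (c == 0) return false;
    rc[k - 1 - i] = c;
  }
  if (rc < out) out = rc;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers, int k) {
  R_xlen_t n = kmers.size();
  CharacterVector res(n);
  std::string can;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(kmers[i]))
      stop("k-mer %d is NA", (int)(i + 1));
    const char* s = CHAR(STRING_ELT(kmers, i));
    int len = (int)LENGTH(STRING_ELT(kmers, i));
    if (len != k)
      stop("k-mer %d has length %d, expected %d", (int)(i + 1), len, k);
    if (!canonical_window(s, k, can))
      stop("k-mer %d contains a character outside {A,C,G,T}", (int)(i + 1));
    res[i] = can;
  }
  return res;
}

// Count canonical k-mers over all length-k windows of all reads. Windows
// containing any non-ACGT character are skipped; reads shorter than k
// contribute nothing. Returns a named integer vector of raw abundances.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector reads, int k) {
  std::unordered_map<std::string, int> counts;
  std::string can;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (CharacterVector::is_na(reads[r])) continue;
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    for (int i = 0; i + k <= len; ++i) {
      if (canonical_window(s + i, k, can)) counts[can] += 1;
    }
  }
  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  R_xlen_t j = 0;
  for (auto& kv : counts) {
    nm[j] = kv.first;
    out[j] = kv.second;
    ++j;
  }
  out.attr("names") = nm;
  return out;
}

// Salted FNV-1a 64-bit hash of each string, reduced modulo num_partitions.
// [[Rcpp::export]]
IntegerVector cpp_partition_of(CharacterVector kmers, int num_partitions,
                               double salt) {
  const uint64_t fnv_offset = 1469598103934665603ULL;
  const uint64_t fnv_prime = 1099511628211ULL;
  uint64_t salt64 = (uint64_t)(int64_t)salt;
  R_xlen_t n = kmers.size();
  IntegerVector res(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(kmers[i]))
      stop("k-mer %d is NA", (int)(i + 1));
    const char* s = CHAR(STRING_ELT(kmers, i));
    uint64_t h = fnv_offset ^ salt64;
    for (const char* p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= fnv_prime;
    }
    res[i] = (int)(h % (uint64_t)num_partitions);
  }
  return res;
}
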