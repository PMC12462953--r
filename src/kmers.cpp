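#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3 (lexicographic order preserved),
// so min(code, revcomp code) equals the lexicographically smaller k-mer.
// -1 = IUPAC ambiguity (window skipped), -2 = invalid character (hard error).
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': case 'R': case 'r': case 'Y': case 'y':
  case 'S': case 's': case 'W': case 'w': case 'K': case 'k':
  case 'M': case 'm': case 'B': case 'b': case 'D': case 'd':
  case 'H': case 'h': case 'V': case 'v': case 'U': case 'u':
    return -1;
  default:
    return -2;
  }
}

// splitmix64 finalizer: well-mixed 64-bit hash of a 2k-bit k-mer code.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_code(uint64_t code, uint64_t seed) {
  return mix64(code ^ mix64(seed));
}

// top 53 bits of the 64-bit hash: exactly representable as an R double
static inline double hash_as_double(uint64_t h) {
  return static_cast<double>(h >> 11);
}

// Scan one sequence, collecting distinct canonical k-mer codes into `out`.
// Windows containing IUPAC-ambiguous bases are skipped; any other character
// raises an error naming its 1-based position.
static void scan_sequence(const char *s, size_t n, int k,
                          std::unordered_set<uint64_t> &out,
                          const char *label) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int filled = 0;
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c == -2)
      stop("invalid character '%c' at position %d in %s",
           s[i], (int)(i + 1), label);
    if (c == -1) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    if (++filled >= k) out.insert(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export]]
NumericVector cpp_canonical_kmer_codes(std::string seq, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> set;
  scan_sequence(seq.c_str(), seq.size(), k, set, "sequence");
  std::vector<uint64_t> v(set.begin(), set.end());
  std::sort(v.begin(), v.end());
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = static_cast<double>(v[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_codes_to_strings(NumericVector codes, int k) {
  static const char bases[] = "ACGT";
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = static_cast<uint64_t>(codes[i]);
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Encode k-mer strings to canonical 2-bit codes (min of both strands).
// [[Rcpp::export]]
NumericVector cpp_strings_to_canonical_codes(CharacterVector kmers, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const int shift_rc = 2 * (k - 1);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k)
      stop("k-mer %d has length != k", (int)(i + 1));
    uint64_t fwd = 0, rev = 0;
    for (int j = 0; j < k; ++j) {
      int c = base_code(s[j]);
      if (c < 0) stop("non-ACGT base in k-mer %d", (int)(i + 1));
      fwd = (fwd << 2) | (uint64_t)c;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
    }
    out[i] = static_cast<double>(fwd < rev ? fwd : rev);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_codes(NumericVector codes, double seed) {
  NumericVector out(codes.size());
  uint64_t s = static_cast<uint64_t>(seed);
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = hash_as_double(hash_code(static_cast<uint64_t>(codes[i]), s));
  return out;
}

// Distinct canonical k-mers of one sequence, hashed; returned sorted
// ascending together with the distinct count.
// [[Rcpp::export]]
List cpp_sketch_sequence(std::string seq, int k, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> set;
  scan_sequence(seq.c_str(), seq.size(), k, set, "sequence");
  uint64_t s = static_cast<uint64_t>(seed);
  std::vector<double> h;
  h.reserve(set.size());
  for (uint64_t code : set) h.push_back(hash_as_double(hash_code(code, s)));
  std::sort(h.begin(), h.end());
  return List::create(_["hashes"] = NumericVector(h.begin(), h.end()),
                      _["total_distinct"] = (double)set.size());
}

// Canonical k-mer counting over a set of reads.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  const int shift_rc = 2 * (k - 1);
  std::unordered_map<uint64_t, double> counts;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    size_t n = (size_t)LENGTH(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int filled = 0;
    for (size_t i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c == -2)
        stop("invalid character '%c' at position %d in read %d",
             s[i], (int)(i + 1), (int)(r + 1));
      if (c == -1) { filled = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++filled >= k) counts[fwd < rev ? fwd : rev] += 1.0;
    }
  }
  std::vector<std::pair<uint64_t, double>> v(counts.begin(), counts.end());
  std::sort(v.begin(), v.end());
  NumericVector code(v.size()), count(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    code[i] = static_cast<double>(v[i].first);
    count[i] = v[i].second;
  }
  return List::create(_["code"] = code, _["count"] = count);
}

// One-SNP pair detection by per-position wildcard bucketing over BOTH
// orientations of each canonical k-mer (so canonicalization cannot hide a
// pair). Returns unique index pairs (1-based, i < j) of k-mers at Hamming
// distance exactly 1 in a consistent orientation.
// [[Rcpp::export]]
IntegerMatrix cpp_find_het_pairs(NumericVector codes, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  R_xlen_t n = codes.size();
  std::vector<uint64_t> fwd(n), rev(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t f = static_cast<uint64_t>(codes[i]), r = 0, tmp = f;
    // consume bases last-to-first; complements append left-to-right
    for (int j = 0; j < k; ++j) {
      r = (r << 2) | (3ULL - (tmp & 3ULL));
      tmp >>= 2;
    }
    fwd[i] = f; rev[i] = r;
  }
  std::unordered_set<uint64_t> seen; // packed (i << 32) | j, i < j
  std::vector<int> pi, pj;
  // sort-based bucketing: one (masked key, index) entry per orientation,
  // sorted, then pairs emitted within runs of equal keys
  std::vector<std::pair<uint64_t, int32_t>> ent((size_t)(2 * n));
  for (int pos = 0; pos < k; ++pos) {
    const uint64_t pmask = ~(3ULL << (2 * pos));
    for (R_xlen_t i = 0; i < n; ++i) {
      ent[(size_t)(2 * i)] = {fwd[i] & pmask, (int32_t)i};
      ent[(size_t)(2 * i + 1)] = {rev[i] & pmask, (int32_t)i};
    }
    std::sort(ent.begin(), ent.end());
    size_t a = 0;
    while (a < ent.size()) {
      size_t b = a + 1;
      while (b < ent.size() && ent[b].first == ent[a].first) ++b;
      for (size_t x = a; x < b; ++x)
        for (size_t y = x + 1; y < b; ++y) {
          int32_t i = ent[x].second, j = ent[y].second;
          if (i == j) continue;
          uint64_t key = i < j
            ? ((uint64_t)i << 32) | (uint64_t)j
            : ((uint64_t)j << 32) | (uint64_t)i;
          if (seen.insert(key).second) {
            pi.push_back((i < j ? i : j) + 1);
            pj.push_back((i < j ? j : i) + 1);
          }
        }
      a = b;
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t i = 0; i < pi.size(); ++i) {
    out(i, 0) = pi[i];
    out(i, 1) = pj[i];
  }
  return out;
}
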