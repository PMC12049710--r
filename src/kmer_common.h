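#ifndef SEQCOASM_KMER_COMMON_H
#define SEQCOASM_KMER_COMMON_H

#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

// 2-bit DNA encoding: A=0, C=1, G=2, T=3 (preserves lexicographic order).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

// Reverse complement of a 2-bit packed k-mer (k <= 31).
static inline uint64_t revcomp_kmer(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2)  & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4)  & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8)  & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

static inline uint64_t canonical_kmer(uint64_t x, int k) {
  uint64_t rc = revcomp_kmer(x, k);
  return x < rc ? x : rc;
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int j = 0; j < k; ++j)
    s[j] = CODE2BASE[(x >> (2 * (k - 1 - j))) & 3ULL];
  return s;
}

// Call f(packed_kmer, start_pos) for every k-mer window of s made of A/C/G/T only.
template <typename F>
static inline void for_each_kmer(const char* s, int len, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t x = 0;
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; x = 0; continue; }
    x = ((x << 2) | (uint64_t)c) & mask;
    if (++run >= k) f(x, i - k + 1);
  }
}

// Position list for one occurrence of a canonical seed.
struct SeedHit {
  int32_t seq;    // sequence (contig/reference) index
  int32_t pos;    // 0-based start on that sequence
  uint8_t fwd;    // 1 if the canonical form equals the forward k-mer at pos
};

typedef std::unordered_map<uint64_t, std::vector<SeedHit> > SeedIndex;

static inline void index_sequences(const std::vector<std::string>& seqs, int k,
                                   SeedIndex& index) {
  for (size_t i = 0; i < seqs.size(); ++i) {
    const std::string& s = seqs[i];
    if ((int)s.size() < k) continue;
    for_each_kmer(s.c_str(), (int)s.size(), k, [&](uint64_t x, int pos) {
      uint64_t canon = canonical_kmer(x, k);
      index[canon].push_back(SeedHit{(int32_t)i, (int32_t)pos,
                                     (uint8_t)(x == canon ? 1 : 0)});
    });
  }
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

#endif
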