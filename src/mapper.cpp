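#include <Rcpp.h>
#include "kmer_common.h"
using namespace Rcpp;

// Seed-vote-and-verify paired-end mapper. Each mate is placed by voting over
// (contig, strand, diagonal) seed hits, then verified by ungapped comparison.

namespace {

struct Placement {
  bool placed;
  int contig;   // 0-based
  int start;    // 0-based start on contig
  int strand;   // 0 = '+', 1 = '-'
  int mm;
};

struct Vote {
  int32_t contig;
  int8_t strand;
  int64_t diag;
  int32_t start;  // candidate contig start implied by this diagonal
  bool operator<(const Vote& o) const {
    if (contig != o.contig) return contig < o.contig;
    if (strand != o.strand) return strand < o.strand;
    return diag < o.diag;
  }
  bool operator==(const Vote& o) const {
    return contig == o.contig && strand == o.strand && diag == o.diag;
  }
};

int count_mismatch(const std::string& read, const std::string& contig,
                   int start, int strand) {
  int L = (int)read.size(), mm = 0;
  if (strand == 0) {
    for (int j = 0; j < L; ++j)
      if (read[j] != contig[start + j]) ++mm;
  } else {
    // read aligns as its reverse complement: read base j pairs with
    // contig base start + L - 1 - j
    for (int j = 0; j < L; ++j)
      if (comp_base(read[j]) != contig[start + L - 1 - j]) ++mm;
  }
  return mm;
}

Placement place_mate(const std::string& read, const std::vector<std::string>& contigs,
                     const SeedIndex& index, int k, double min_seed_frac,
                     double max_mm_frac) {
  Placement none = {false, -1, -1, 0, 0};
  int L = (int)read.size();
  if (L < k) return none;
  int n_seeds = L - k + 1;

  std::vector<Vote> votes;
  votes.reserve(n_seeds);
  for_each_kmer(read.c_str(), L, k, [&](uint64_t x, int rp) {
    uint64_t canon = canonical_kmer(x, k);
    SeedIndex::const_iterator it = index.find(canon);
    if (it == index.end()) return;
    bool read_fwd = (x == canon);
    for (size_t h = 0; h < it->second.size(); ++h) {
      const SeedHit& hit = it->second[h];
      int strand = (read_fwd == (bool)hit.fwd) ? 0 : 1;
      int64_t diag = strand == 0 ? (int64_t)hit.pos - rp : (int64_t)hit.pos + rp;
      int32_t start = strand == 0 ? (int32_t)diag : (int32_t)(diag - L + k);
      votes.push_back(Vote{hit.seq, (int8_t)strand, diag, start});
    }
  });
  if (votes.empty()) return none;

  std::sort(votes.begin(), votes.end());
  // pick best-supported diagonal; ties: lowest contig, then leftmost start,
  // then '+' strand (sort order already yields this scan order)
  size_t best_i = 0, best_n = 0;
  size_t i = 0;
  while (i < votes.size()) {
    size_t j = i;
    while (j < votes.size() && votes[j] == votes[i]) ++j;
    size_t n = j - i;
    bool better = n > best_n;
    if (n == best_n && best_n > 0) {
      const Vote &a = votes[i], &b = votes[best_i];
      if (a.contig < b.contig ||
          (a.contig == b.contig && a.start < b.start) ||
          (a.contig == b.contig && a.start == b.start && a.strand < b.strand))
        better = true;
    }
    if (better) { best_i = i; best_n = n; }
    i = j;
  }
  int min_hits = (int)std::ceil(min_seed_frac * n_seeds);
  if (min_hits < 1) min_hits = 1;
  if ((int)best_n < min_hits) return none;

  const Vote& v = votes[best_i];
  const std::string& ctg = contigs[v.contig];
  if (v.start < 0 || v.start + L > (int)ctg.size()) return none;
  int mm = count_mismatch(read, ctg, v.start, v.strand);
  if (mm > (int)std::floor(max_mm_frac * L)) return none;
  return Placement{true, v.contig, v.start, v.strand, mm};
}

} // namespace

// status codes: 1 concordant, 2 discordant, 3 mate1_only, 4 mate2_only, 5 unaligned
// [[Rcpp::export]]
List cpp_map_pairs(CharacterVector contigs, CharacterVector m1, CharacterVector m2,
                   int k, double min_seed_frac, double max_mm_frac,
                   int ins_min, int ins_max) {
  if (m1.size() != m2.size()) stop("mate vectors differ in length");
  std::vector<std::string> ctg(contigs.size());
  for (R_xlen_t i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  SeedIndex index;
  index_sequences(ctg, k, index);

  R_xlen_t n = m1.size();
  IntegerVector status(n), c1(n), s1(n), st1(n), mm1(n), c2(n), s2(n), st2(n), mm2(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(m1[i]);
    std::string r2 = as<std::string>(m2[i]);
    Placement p1 = place_mate(r1, ctg, index, k, min_seed_frac, max_mm_frac);
    Placement p2 = place_mate(r2, ctg, index, k, min_seed_frac, max_mm_frac);

    int code;
    if (p1.placed && p2.placed) {
      code = 2;  // discordant unless proven concordant
      if (p1.contig == p2.contig && p1.strand != p2.strand) {
        const Placement& plus = p1.strand == 0 ? p1 : p2;
        const Placement& minus = p1.strand == 0 ? p2 : p1;
        int L_minus = (int)(p1.strand == 0 ? r2 : r1).size();
        int frag = (minus.start + L_minus) - plus.start;   // FR insert size
        if (plus.start <= minus.start && frag >= ins_min && frag <= ins_max)
          code = 1;
      }
    } else if (p1.placed) {
      code = 3;
    } else if (p2.placed) {
      code = 4;
    } else {
      code = 5;
    }
    status[i] = code;
    c1[i] = p1.placed ? p1.contig + 1 : NA_INTEGER;
    s1[i] = p1.placed ? p1.start : NA_INTEGER;
    st1[i] = p1.placed ? p1.strand : NA_INTEGER;
    mm1[i] = p1.placed ? p1.mm : NA_INTEGER;
    c2[i] = p2.placed ? p2.contig + 1 : NA_INTEGER;
    s2[i] = p2.placed ? p2.start : NA_INTEGER;
    st2[i] = p2.placed ? p2.strand : NA_INTEGER;
    mm2[i] = p2.placed ? p2.mm : NA_INTEGER;
  }
  return List::create(
    _["status"] = status,
    _["contig1"] = c1, _["start1"] = s1, _["strand1"] = st1, _["mismatch1"] = mm1,
    _["contig2"] = c2, _["start2"] = s2, _["strand2"] = st2, _["mismatch2"] = mm2);
}

// [[Rcpp::export]]
DataFrame cpp_lookup_seed(CharacterVector contigs, int k, std::string seed) {
  if ((int)seed.size() != k) stop("seed length must equal k");
  std::vector<std::string> ctg(contigs.size());
  for (R_xlen_t i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  SeedIndex index;
  index_sequences(ctg, k, index);
  uint64_t x = 0;
  for (int j = 0; j < k; ++j) {
    int c = base_code(seed[j]);
    if (c < 0) stop("seed contains a non-ACGT character");
    x = (x << 2) | (uint64_t)c;
  }
  bool fwd_is_canon = (x == canonical_kmer(x, k));
  uint64_t canon = canonical_kmer(x, k);
  std::vector<int> contig, pos;
  std::vector<std::string> strand;
  SeedIndex::const_iterator it = index.find(canon);
  if (it != index.end()) {
    for (size_t h = 0; h < it->second.size(); ++h) {
      contig.push_back(it->second[h].seq + 1);
      pos.push_back(it->second[h].pos);
      strand.push_back((fwd_is_canon == (bool)it->second[h].fwd) ? "+" : "-");
    }
  }
  return DataFrame::create(_["contig"] = wrap(contig), _["pos"] = wrap(pos),
                           _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}
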