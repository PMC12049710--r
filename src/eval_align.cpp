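#include <Rcpp.h>
#include "kmer_common.h"
using namespace Rcpp;

// Contig-to-reference block alignment: exact k-mer anchors grouped by
// (reference, strand, diagonal), hulls extended by exact match at both ends,
// mismatches counted inside blocks, greedy non-overlapping selection per contig.

namespace {

struct Anchor {
  int32_t ref;
  int8_t strand;   // 0 '+', 1 '-'
  int64_t diag;    // '+': rpos - cpos ; '-': rpos + cpos
  int32_t cpos;
  bool operator<(const Anchor& o) const {
    if (ref != o.ref) return ref < o.ref;
    if (strand != o.strand) return strand < o.strand;
    if (diag != o.diag) return diag < o.diag;
    return cpos < o.cpos;
  }
};

struct Block {
  int32_t contig, ref;
  int64_t cs, ce, rs, re;  // half-open intervals
  int8_t strand;
  int32_t mm;
  int64_t len() const { return ce - cs; }
};

Block make_block(int contig, const Anchor& a, int64_t cs, int64_t ce, int k,
                 const std::string& ctg, const std::string& ref) {
  Block b;
  b.contig = contig;
  b.ref = a.ref;
  b.strand = a.strand;
  b.cs = cs;
  b.ce = ce;
  if (a.strand == 0) {
    b.rs = a.diag + cs;
    b.re = a.diag + ce;
  } else {
    b.rs = a.diag + k - ce;
    b.re = a.diag + k - cs;
  }
  int64_t clen = (int64_t)ctg.size(), rlen = (int64_t)ref.size();
  // extend ends while bases match exactly
  if (a.strand == 0) {
    while (b.cs > 0 && b.rs > 0 && ctg[b.cs - 1] == ref[b.rs - 1]) { --b.cs; --b.rs; }
    while (b.ce < clen && b.re < rlen && ctg[b.ce] == ref[b.re]) { ++b.ce; ++b.re; }
  } else {
    // contig base c pairs with complement of ref base (diag + k - 1 - c)
    while (b.cs > 0 && b.re < rlen && ref[b.re] == comp_base(ctg[b.cs - 1])) {
      --b.cs; ++b.re;
    }
    while (b.ce < clen && b.rs > 0 && ref[b.rs - 1] == comp_base(ctg[b.ce])) {
      ++b.ce; --b.rs;
    }
  }
  // mismatches inside the block
  b.mm = 0;
  if (a.strand == 0) {
    int64_t off = b.rs - b.cs;
    for (int64_t c = b.cs; c < b.ce; ++c)
      if (ctg[c] != ref[c + off]) ++b.mm;
  } else {
    int64_t A = a.diag + k - 1;
    for (int64_t c = b.cs; c < b.ce; ++c)
      if (ctg[c] != comp_base(ref[A - c])) ++b.mm;
  }
  return b;
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_align_contigs(CharacterVector contigs, CharacterVector refs,
                            int k, int min_block, int max_anchor_gap) {
  std::vector<std::string> ctg(contigs.size()), rf(refs.size());
  for (R_xlen_t i = 0; i < contigs.size(); ++i) ctg[i] = as<std::string>(contigs[i]);
  for (R_xlen_t i = 0; i < refs.size(); ++i) rf[i] = as<std::string>(refs[i]);
  SeedIndex index;
  index_sequences(rf, k, index);

  std::vector<Block> out;
  for (size_t ci = 0; ci < ctg.size(); ++ci) {
    const std::string& c = ctg[ci];
    if ((int)c.size() < k) continue;
    std::vector<Anchor> anchors;
    for_each_kmer(c.c_str(), (int)c.size(), k, [&](uint64_t x, int cpos) {
      uint64_t canon = canonical_kmer(x, k);
      SeedIndex::const_iterator it = index.find(canon);
      if (it == index.end()) return;
      bool cf = (x == canon);
      for (size_t h = 0; h < it->second.size(); ++h) {
        const SeedHit& hit = it->second[h];
        int strand = (cf == (bool)hit.fwd) ? 0 : 1;
        int64_t diag = strand == 0 ? (int64_t)hit.pos - cpos
                                   : (int64_t)hit.pos + cpos;
        anchors.push_back(Anchor{hit.seq, (int8_t)strand, diag, (int32_t)cpos});
      }
    });
    if (anchors.empty()) continue;
    std::sort(anchors.begin(), anchors.end());

    std::vector<Block> cand;
    size_t i = 0;
    while (i < anchors.size()) {
      size_t j = i + 1;
      while (j < anchors.size() && anchors[j].ref == anchors[i].ref &&
             anchors[j].strand == anchors[i].strand &&
             anchors[j].diag == anchors[i].diag &&
             anchors[j].cpos - anchors[j - 1].cpos <= max_anchor_gap)
        ++j;
      Block b = make_block((int)ci, anchors[i], anchors[i].cpos,
                           (int64_t)anchors[j - 1].cpos + k, k, c, rf[anchors[i].ref]);
      if (b.len() >= min_block) cand.push_back(b);
      i = j;
    }
    // greedy: longest first (ties: leftmost, then lowest ref, then '+')
    std::sort(cand.begin(), cand.end(), [](const Block& a, const Block& b) {
      if (a.len() != b.len()) return a.len() > b.len();
      if (a.cs != b.cs) return a.cs < b.cs;
      if (a.ref != b.ref) return a.ref < b.ref;
      return a.strand < b.strand;
    });
    // Keep blocks non-overlapping on the contig: each candidate is trimmed to
    // the largest still-free contig interval it intersects (trimming moves
    // block ends but never the diagonal, so downstream gap arithmetic between
    // adjacent blocks is unaffected).
    std::vector<Block> acc;
    for (size_t bi = 0; bi < cand.size(); ++bi) {
      Block b = cand[bi];
      std::vector<std::pair<int64_t, int64_t> > used;
      for (size_t ai = 0; ai < acc.size(); ++ai)
        if (cand[bi].cs < acc[ai].ce && acc[ai].cs < cand[bi].ce)
          used.push_back(std::make_pair(acc[ai].cs, acc[ai].ce));
      if (!used.empty()) {
        std::sort(used.begin(), used.end());
        // free gaps inside [b.cs, b.ce) around the used intervals
        int64_t best_s = 0, best_e = 0, cur = b.cs;
        for (size_t ui = 0; ui <= used.size(); ++ui) {
          int64_t gap_e = (ui < used.size()) ? std::min(used[ui].first, b.ce)
                                             : b.ce;
          if (gap_e - cur > best_e - best_s) { best_s = cur; best_e = gap_e; }
          if (ui < used.size()) cur = std::max(cur, used[ui].second);
        }
        if (best_e - best_s < min_block) continue;
        int64_t dl = best_s - b.cs, dr = b.ce - best_e;
        if (b.strand == 0) { b.rs += dl; b.re -= dr; }
        else               { b.rs += dr; b.re -= dl; }
        b.cs = best_s;
        b.ce = best_e;
        // recount mismatches over the trimmed interval
        b.mm = 0;
        const std::string& ref = rf[b.ref];
        if (b.strand == 0) {
          int64_t off = b.rs - b.cs;
          for (int64_t cc = b.cs; cc < b.ce; ++cc)
            if (c[cc] != ref[cc + off]) ++b.mm;
        } else {
          int64_t A = b.re - 1 + b.cs;  // ref index of contig base b.cs
          for (int64_t cc = b.cs; cc < b.ce; ++cc)
            if (c[cc] != comp_base(ref[A - cc])) ++b.mm;
        }
      }
      if (b.len() >= min_block) acc.push_back(b);
    }
    std::sort(acc.begin(), acc.end(), [](const Block& a, const Block& b) {
      return a.cs < b.cs;
    });
    out.insert(out.end(), acc.begin(), acc.end());
  }

  R_xlen_t n = (R_xlen_t)out.size();
  IntegerVector contig(n), ref(n), mm(n);
  NumericVector cs(n), ce(n), rs(n), re(n);
  CharacterVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    contig[i] = out[i].contig + 1;
    ref[i] = out[i].ref + 1;
    cs[i] = (double)out[i].cs;
    ce[i] = (double)out[i].ce;
    rs[i] = (double)out[i].rs;
    re[i] = (double)out[i].re;
    strand[i] = out[i].strand == 0 ? "+" : "-";
    mm[i] = out[i].mm;
  }
  return DataFrame::create(
    _["contig"] = contig, _["contig_start"] = cs, _["contig_end"] = ce,
    _["ref"] = ref, _["ref_start"] = rs, _["ref_end"] = re,
    _["strand"] = strand, _["mismatches"] = mm,
    _["stringsAsFactors"] = false);
}
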