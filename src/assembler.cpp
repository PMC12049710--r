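#include <Rcpp.h>
#include "kmer_common.h"
using namespace Rcpp;

// Canonical de Bruijn graph over the filtered k-mer set, plus unitig traversal.
// Nodes are canonical k-mers; an oriented node is (index, rc) where rc = 1 means
// the node is traversed as the reverse complement of its stored canonical form.

namespace {

struct Oriented {
  uint32_t idx;
  uint8_t rc;
};

struct Graph {
  std::vector<uint64_t> kmers;                    // sorted canonical k-mers
  std::unordered_map<uint64_t, uint32_t> pos;     // k-mer -> index in kmers
  int k;
  uint64_t mask;

  uint64_t seq_of(const Oriented& o) const {
    return o.rc ? revcomp_kmer(kmers[o.idx], k) : kmers[o.idx];
  }

  int successors(const Oriented& o, Oriented out[4]) const {
    uint64_t s = seq_of(o);
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nxt = ((s << 2) | b) & mask;
      uint64_t rc = revcomp_kmer(nxt, k);
      uint64_t canon = nxt < rc ? nxt : rc;
      std::unordered_map<uint64_t, uint32_t>::const_iterator it = pos.find(canon);
      if (it != pos.end())
        out[n++] = Oriented{it->second, (uint8_t)(nxt == canon ? 0 : 1)};
    }
    return n;
  }

  int pred_count(const Oriented& o) const {
    Oriented flip = {o.idx, (uint8_t)(1 - o.rc)};
    Oriented tmp[4];
    return successors(flip, tmp);
  }
};

// Extend a maximal non-branching walk from cur; newly visited nodes are appended.
void extend_walk(const Graph& G, Oriented cur, std::vector<char>& visited,
                 std::vector<Oriented>& path) {
  for (;;) {
    Oriented succ[4];
    int ns = G.successors(cur, succ);
    if (ns != 1) break;
    Oriented nxt = succ[0];
    if (visited[nxt.idx]) break;           // stops cycles and hairpins
    if (G.pred_count(nxt) != 1) break;     // nxt is a merge point: unitig ends
    visited[nxt.idx] = 1;
    path.push_back(nxt);
    cur = nxt;
  }
}

std::string path_to_seq(const Graph& G, const std::vector<Oriented>& nodes) {
  std::string s = decode_kmer(G.seq_of(nodes[0]), G.k);
  for (size_t i = 1; i < nodes.size(); ++i)
    s.push_back(CODE2BASE[G.seq_of(nodes[i]) & 3ULL]);
  return s;
}

void count_kmers(const CharacterVector& reads, int k,
                 std::unordered_map<uint64_t, uint32_t>& counts,
                 int& n_short, int& n_used) {
  n_short = 0;
  n_used = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    if (len < k) { ++n_short; continue; }
    ++n_used;
    for_each_kmer(s, len, k, [&](uint64_t x, int) {
      ++counts[canonical_kmer(x, k)];
    });
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_count, int min_contig_len) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  int n_short = 0, n_used = 0;
  count_kmers(reads, k, counts, n_short, n_used);

  Graph G;
  G.k = k;
  G.mask = (1ULL << (2 * k)) - 1ULL;
  G.kmers.reserve(counts.size());
  for (std::unordered_map<uint64_t, uint32_t>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    if ((int)it->second >= min_count) G.kmers.push_back(it->first);
  std::sort(G.kmers.begin(), G.kmers.end());
  G.pos.reserve(G.kmers.size() * 2);
  for (uint32_t i = 0; i < G.kmers.size(); ++i) G.pos[G.kmers[i]] = i;

  std::vector<std::string> contigs;
  std::vector<char> visited(G.kmers.size(), 0);
  for (uint32_t i = 0; i < G.kmers.size(); ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    Oriented start = {i, 0};
    std::vector<Oriented> right, left;
    extend_walk(G, start, visited, right);
    extend_walk(G, Oriented{i, 1}, visited, left);
    // full path: reverse-complemented left walk, start, right walk
    std::vector<Oriented> path;
    path.reserve(left.size() + 1 + right.size());
    for (std::vector<Oriented>::reverse_iterator it = left.rbegin();
         it != left.rend(); ++it)
      path.push_back(Oriented{it->idx, (uint8_t)(1 - it->rc)});
    path.push_back(start);
    path.insert(path.end(), right.begin(), right.end());
    std::string seq = path_to_seq(G, path);
    if ((int)seq.size() < min_contig_len) continue;
    std::string rc = revcomp_str(seq);
    contigs.push_back(seq <= rc ? seq : rc);   // deterministic orientation
  }
  // deterministic order: length descending, then sequence ascending
  std::sort(contigs.begin(), contigs.end(),
            [](const std::string& a, const std::string& b) {
              if (a.size() != b.size()) return a.size() > b.size();
              return a < b;
            });

  return List::create(
    _["contigs"] = wrap(contigs),
    _["n_kmers_distinct"] = (double)counts.size(),
    _["n_kmers_kept"] = (double)G.kmers.size(),
    _["n_reads_used"] = n_used,
    _["n_reads_short"] = n_short);
}

// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector reads, int k, int min_count) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  int n_short = 0, n_used = 0;
  count_kmers(reads, k, counts, n_short, n_used);
  std::vector<std::pair<uint64_t, uint32_t> > kept;
  for (std::unordered_map<uint64_t, uint32_t>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    if ((int)it->second >= min_count) kept.push_back(*it);
  std::sort(kept.begin(), kept.end());
  CharacterVector kmers(kept.size());
  IntegerVector cnt(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    kmers[i] = decode_kmer(kept[i].first, k);
    cnt[i] = (int)kept[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt,
                      _["n_reads_short"] = n_short, _["n_reads_used"] = n_used);
}

// [[Rcpp::export]]
NumericVector cpp_kmer_histogram(CharacterVector reads, int k, int max_count) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  int n_short = 0, n_used = 0;
  count_kmers(reads, k, counts, n_short, n_used);
  NumericVector h(max_count);  // h[c-1] = number of distinct k-mers with count c (capped)
  for (std::unordered_map<uint64_t, uint32_t>::const_iterator it = counts.begin();
       it != counts.end(); ++it) {
    int c = (int)it->second;
    if (c > max_count) c = max_count;
    h[c - 1] += 1;
  }
  return h;
}
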