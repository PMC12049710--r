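#include <Rcpp.h>
#include "kmer_common.h"
#include <random>
#include <cmath>
using namespace Rcpp;

// Per-sample paired-end read simulation. All randomness comes from a
// std::mt19937_64 stream with hand-written uniform / Box-Muller transforms so
// output is byte-identical across platforms and standard libraries.

namespace {

struct Rng {
  std::mt19937_64 eng;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : eng(seed), have_spare(false), spare(0.0) {}
  double unif() {  // in [0, 1)
    return (double)(eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // in [0, n)
    return (int)(unif() * (double)n);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

char mutate(char base, double v) {
  // v in [0,1): pick one of the three other bases
  static const char* others[4] = {"CGT", "AGT", "ACT", "ACG"};
  int c = base_code(base);
  if (c < 0) return base;
  return others[c][(int)(v * 3.0)];
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate_sample(CharacterVector genomes, NumericVector probs,
                         int n_pairs, int read_len, double ins_mean,
                         double ins_sd, double err_rate, double seed) {
  R_xlen_t ng = genomes.size();
  if (probs.size() != ng) stop("probs length must match genomes");
  std::vector<std::string> gen(ng);
  for (R_xlen_t i = 0; i < ng; ++i) gen[i] = as<std::string>(genomes[i]);
  std::vector<double> cum(ng);
  double tot = 0.0;
  for (R_xlen_t i = 0; i < ng; ++i) {
    if (probs[i] < 0) stop("negative probability");
    tot += probs[i];
    cum[i] = tot;
  }
  if (tot <= 0) stop("probabilities sum to zero");
  for (R_xlen_t i = 0; i < ng; ++i) {
    cum[i] /= tot;
    if (probs[i] > 0 && (int)gen[i].size() < read_len)
      stop("genome shorter than the read length has positive abundance");
  }

  Rng rng((uint64_t)seed);
  CharacterVector m1(n_pairs), m2(n_pairs);
  IntegerVector origin(n_pairs), start(n_pairs);
  CharacterVector strand(n_pairs);
  std::string frag, r1, r2;

  for (int p = 0; p < n_pairs; ++p) {
    double u = rng.unif();
    int g = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (g >= (int)ng) g = (int)ng - 1;
    const std::string& G = gen[g];
    int glen = (int)G.size();

    int ins = 0;
    bool ok = false;
    for (int attempt = 0; attempt < 64; ++attempt) {
      ins = (int)std::llround(ins_mean + ins_sd * rng.norm());
      if (ins < read_len) ins = read_len;
      if (ins <= glen) { ok = true; break; }
    }
    if (!ok) {
      if (glen >= read_len) ins = glen;  // fall back to a full-length fragment
      else stop("cannot draw a fragment from genome %d", g + 1);
    }

    int s = rng.unif_int(glen - ins + 1);
    frag.assign(G, s, ins);
    int fwd = rng.unif() < 0.5 ? 1 : 0;
    if (fwd) {
      r1.assign(frag, 0, read_len);
      r2 = revcomp_str(frag.substr(ins - read_len, read_len));
    } else {
      r1 = revcomp_str(frag.substr(ins - read_len, read_len));
      r2.assign(frag, 0, read_len);
    }
    if (err_rate > 0) {
      for (int j = 0; j < read_len; ++j)
        if (rng.unif() < err_rate) r1[j] = mutate(r1[j], rng.unif());
      for (int j = 0; j < read_len; ++j)
        if (rng.unif() < err_rate) r2[j] = mutate(r2[j], rng.unif());
    }
    m1[p] = r1;
    m2[p] = r2;
    origin[p] = g + 1;
    start[p] = s;
    strand[p] = fwd ? "+" : "-";
  }
  return List::create(_["mate1"] = m1, _["mate2"] = m2, _["origin"] = origin,
                      _["start"] = start, _["strand"] = strand);
}

// [[Rcpp::export]]
std::string cpp_random_sequence(int len, double gc, double seed) {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)");
  Rng rng((uint64_t)seed);
  double at = (1.0 - gc) / 2.0, g = gc / 2.0;
  double c1 = at, c2 = at + g, c3 = at + 2 * g;  // A | C | G | T
  std::string s(len, 'A');
  for (int i = 0; i < len; ++i) {
    double u = rng.unif();
    s[i] = u < c1 ? 'A' : (u < c2 ? 'C' : (u < c3 ? 'G' : 'T'));
  }
  return s;
}
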