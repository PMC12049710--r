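---
title: "Sequential co-assembly: method, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential co-assembly: method, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcoasm)
```

## The problem

Multi-sample shotgun metagenome studies usually pool all samples' reads into
one *co-assembly* so that low-abundance organisms, whose reads are spread
thinly across samples, accumulate enough coverage to assemble. The cost is
that the dominant organisms — which are often shared across samples — are
sequenced far past the depth needed for their assembly, so the pooled input is
mostly redundant. For a three-organism community at 90/5/5 relative abundance
needing 10,000 reads per genome, total depth must reach
`required_depth(c(.9,.05,.05), 10000)` = 200,000 reads, of which 85% are
redundant copies of the dominant genome (`excess_reads()`); an even community
would need only 30,000. Redundancy grows with unevenness and directly inflates
assembler time and memory.

*Sequential co-assembly* removes that redundancy in three steps:

1. **Seed assembly.** Co-assemble a small subset of samples. This recovers the
   abundant, ubiquitous genomes cheaply.
2. **Read subtraction.** Map *every* sample's pairs to the seed assembly.
   Pairs that align *concordantly* (both mates on one contig, FR orientation,
   insert within the expected window) are "uninformative": their genomes are
   already assembled. All other pairs — discordant, single-mate, unaligned —
   are retained, mirroring the `--un-conc-gz` convention of common aligners.
3. **Final assembly.** Co-assemble the subset samples' full raw pairs together
   with the retained pools of the remaining samples. Subset samples are
   re-mapped in step 2 like everyone else, but their raw reads enter step 3
   unconditionally and their pools are excluded from the union so no pair is
   counted twice.

The package implements the full loop — community simulation with per-read
ground truth, a bundled deterministic assembler and paired-end mapper, the
three-step orchestration, and a reference-based plus reference-free evaluation
suite — so the method's claims (comparable genome recovery, smaller final
input, fewer redundant bases) are testable properties rather than anecdotes.

## The simulator and what it does (not) emulate

`generate_genomes()` draws i.i.d. random genomes (no N, uniform length in a
range, target GC). `assign_abundances()` builds a sample-by-taxon relative
abundance matrix with the structure the method assumes: a steep, log-like
ranked abundance distribution (i.i.d. lognormal base abundances, default
`sdlog = 1.5`, ranked; or a log-series option), a *core* of taxa present in
every sample, and non-core taxa present in a Bernoulli(0.3) subset of samples.
The core is taken from the top of the abundance ranking, reproducing the
canonical mock picture: one dominant organism everywhere, rare organisms
patchy. Per-sample abundances jitter the base values multiplicatively
(`sample_sdlog = 0.5`) and renormalise.

`simulate_reads()` draws each pair's origin genome multinomially with
probability proportional to abundance × genome length — organismal abundance
times genome size is what shotgun read share actually tracks — with an
`weighted = FALSE` switch that equates read share with abundance so the
worked depth-planning examples hold exactly. Fragments are uniform along the
genome, Gaussian insert length (default 300 ± 30 bp), FR orientation from a
random strand, i.i.d. substitution errors (default 0.2%), constant 'I'
quality. Coordinates are 0-based half-open; truth records the fragment's
forward-strand start. One master seed; per-sample streams are derived by
fixed offsets, so adding samples never changes earlier samples' reads. All
random draws happen in a self-contained Mersenne-Twister stream with
hand-written transforms, so output is byte-identical across platforms.

What it deliberately does **not** emulate: indels, chimeric fragments, PCR
duplicates, platform quality profiles, host contamination, or strain-level
variation. Passing tests therefore demonstrate the *pipeline logic* — read
accounting, subtraction semantics, recovery parity under substitution noise —
not robustness to every artifact of real sequencing. External assembler and
mapper backends can be slotted behind the same interfaces for real data.

`tile_read_pairs()` complements the random simulator with a deterministic
deep-tiling generator (every fragment start, a configurable number of copies).
Random fragment starts leave a linear genome's terminal k-mers under-covered
with non-vanishing probability at any finite depth, so exact-reconstruction
oracles use tiling, which guarantees every k-mer at least `copies`-fold
coverage.

## The bundled assembler

`assemble_reads()` is a single-k de Bruijn unitig assembler over canonical
k-mers (k odd, default 31, so no k-mer is its own reverse complement).
K-mers below `min_count` are dropped; contigs are maximal non-branching paths,
with each surviving k-mer placed in exactly one contig. There is no bubble
popping, tip clipping or multi-k iteration: any branch ends a unitig. That
keeps the output exactly characterised by the graph — checkable against a
brute-force oracle — and fully deterministic (unitigs are emitted in their
lexicographically smaller orientation, ordered by length then sequence).

Two consequences deserve attention:

* **Hairpins.** If a sequence contains a k-mer and its reverse complement
  (common at toy k, vanishing at k = 31), the canonical walk meets the same
  node in both orientations and stops; such fixtures legitimately yield
  shorter unitigs than a directed-graph hand derivation would suggest.
* **Deep coverage and errors.** A substitution seen twice at the same genome
  position creates a k-mer of count ≥ 2; with hundreds-fold coverage such
  duplicated error k-mers become common, and — with no tip clipping — each one
  branches and terminates a unitig. A fixed `min_count = 2` therefore shreds
  exactly the deepest genomes. `min_count = "auto"` addresses this with the
  classical count-spectrum rule: take the histogram of canonical k-mer
  multiplicities and cut at the first count where it stops decreasing — the
  valley after the monotone error tail. If the data has no singleton k-mers
  (no error tail), the cutoff falls back to 2. The cutoff trades the deepest
  genomes' integrity against taxa whose k-mer coverage sits below the valley;
  at the simulated study's depth the valley falls around 4–5, which removes
  the error branches while keeping every taxon above ~10× base coverage.

## The paired-end mapper

`build_map_index()` indexes every canonical 31-mer of the contigs with its
positions. `map_read_pairs()` places each mate by seed voting — the
most-supported (contig, strand, diagonal), requiring at least 25% of the
mate's seeds — then verifies by ungapped comparison allowing a 5% mismatch
fraction. Ties break deterministically (lowest contig, leftmost, '+').
Pair statuses follow the concordant-pair convention; `partition_sample()`
subtracts concordant pairs only (a `keep_discordant = FALSE` switch subtracts
discordant pairs too, since the convention the method inherits does not
settle that case). *Overall read alignment* is the percentage of mates
(reads, not pairs) with at least one placement — an explicit stand-in for the
multi-category "overall alignment rate" of production aligners, not a claim
of numeric equivalence to it. The defaults (insert window = simulated mean
± 4 sd, 5% mismatch) are permissive enough to absorb the simulator's
substitution errors; there is no gapped alignment because the simulator emits
no indels.

## Evaluation

`align_contigs()` aligns contigs to references by exact 31-mer anchors grouped
per (reference, strand, diagonal) into ungapped blocks, extended at both ends
by exact match, with mismatches counted inside blocks; blocks under 65 bp are
discarded, and a greedy longest-first selection keeps blocks non-overlapping
on the contig, trimming newcomers to the largest free interval (trimming moves
block ends, never diagonals, so gap arithmetic is unaffected). From the
blocks:

* `genome_fraction()` — % of reference bases covered by ≥ 1 block (union;
  multiplicity is deliberately ignored here);
* `duplication_ratio()` — aligned contig bases / covered reference bases;
* `count_misassemblies()` — adjacent blocks in a contig that switch reference
  or strand, or disagree positionally by ≥ 1000 bp, are extensive
  misassemblies; disagreements of 50–999 bp are local. These boundary values
  follow the convention family of mainstream assembly evaluators and are
  exposed as arguments, since the exact boundaries are a declared choice;
* `mismatches_per_100kbp()`, `contiguity_stats()` (auN = ΣL²/ΣL, N50, total
  length ≥ 50 kbp).

`read_alignment_eval()` is the reference-free counterpart: the distribution of
overall read alignment across samples. Across strategies, its mean tracks the
cumulative length-weighted abundance of the taxa an assembly covers — the
reason read alignment works as a recovery proxy when no references exist —
and `fit_alignment_model()` fits the corresponding linear model of mean
alignment against log genome fraction.

## Comparing strategies fairly

`compare_strategies()` evaluates each run against the same references and
read sets. One design rule matters: **assembler parameters are fixed across
strategies within a comparison**. The spectrum cutoff is chosen once from the
pooled dataset and passed to every run (subset-only, sequential steps 1 and 3,
traditional). Letting each run auto-pick its own cutoff lets two strategies
land on adjacent valleys and diverge on border-coverage genomes — a
parameter artifact, not a property of the strategies.

The bundled study (also what `scripts/acceptance.R` reruns) uses 20 genomes of
5–20 kbp, lognormal abundances with a 25% core, 10 samples × 20,000 pairs,
0.2% substitution error, and a 3-sample subset — about 250 kbp of community
and 4 Gbp-scale structure in miniature, sized so the whole study runs in a few
minutes on one CPU. Under those conditions the sequential and traditional
genome fractions agree within a fraction of a percentage point, both exceed
the subset-only assembly's read alignment, and the step-3 input is roughly
40% of the total pairs.

## Numerical and degenerate-input choices

* `expected_reads()` apportions fractional expectations by largest remainder
  (ties to the later entry) so counts always sum to the requested depth.
* Zero-abundance organisms make `required_depth()` error: no finite depth
  reaches them.
* Empty assemblies evaluate to 0% genome fraction and `NA` duplication ratio
  (nothing aligned to divide by); empty samples partition to an empty pool
  with 0% alignment and a warning.
* Fragments longer than their genome are resampled a bounded number of times,
  then fall back to a genome-length fragment.
* Every tie anywhere (unitig orientation, contig order, mapping candidates,
  block selection) is broken lexicographically or by position so reruns are
  byte-identical.

## Known limitations

Single-k assembly underperforms multi-k production assemblers at low coverage;
the mapper is ungapped and best-hit only; the evaluator has no gapped or
split alignment and no ambiguity-resolution policy for near-identical
references; replicate-to-replicate assembler variance (a motivation for
triplicate runs with external tools) cannot be exercised internally because
the bundled assembler is exactly deterministic. These are scope boundaries,
not accidents: each component is the smallest faithful stand-in that keeps
the sequential method's bookkeeping — which is the object of study — exact
and verifiable.
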