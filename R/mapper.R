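#' Mapper parameter bundle
#'
#' Defaults are permissive enough to absorb the simulator's substitution
#' errors: 31-bp seeds, a mate is placed when at least `min_seed_frac` of its
#' seeds vote for one (contig, strand, diagonal) and ungapped verification
#' finds at most `max_mismatch_frac` mismatching bases. The insert window is
#' the simulated mean +/- 4 sd by default.
#'
#' @param k_index Seed length in bp.
#' @param min_seed_frac Minimum fraction of a mate's seeds supporting the
#'   winning diagonal.
#' @param max_mismatch_frac Maximum mismatch fraction over the mate length.
#' @param insert_window Concordant insert-size interval `c(min, max)` in bp.
#' @return A list of mapper parameters.
#' @export
map_params <- function(k_index = 31, min_seed_frac = 0.25,
                       max_mismatch_frac = 0.05,
                       insert_window = c(180, 420)) {
  stopifnot(k_index >= 3, length(insert_window) == 2,
            insert_window[1] <= insert_window[2])
  list(k_index = as.integer(k_index), min_seed_frac = min_seed_frac,
       max_mismatch_frac = max_mismatch_frac,
       insert_window = as.integer(insert_window))
}

#' Build a seed index over an assembly
#'
#' Indexes every canonical `k_index`-mer of every contig with its positions.
#' Contigs shorter than `k_index` are skipped with a warning.
#'
#' @param assembly An `assembly` tibble (or named character vector of contigs).
#' @param k_index Seed length in bp.
#' @return A `map_index` (contig sequences, lengths, seed length, position
#'   count). Seed lookups use [lookup_seed()].
#' @export
build_map_index <- function(assembly, k_index = 31) {
  contigs <- contig_seqs(assembly)
  if (length(contigs) == 0) abort("cannot index an empty assembly")
  short <- nchar(contigs) < k_index
  if (any(short)) {
    warn(sprintf("%d contigs shorter than k_index = %d were skipped",
                 sum(short), k_index))
    contigs <- contigs[!short]
  }
  if (length(contigs) == 0) abort("all contigs are shorter than k_index")
  structure(
    list(contigs = contigs, lengths = nchar(contigs),
         k_index = as.integer(k_index),
         n_positions = sum(nchar(contigs) - k_index + 1L)),
    class = "map_index")
}

#' @export
print.map_index <- function(x, ...) {
  cat("Seed index:", length(x$contigs), "contigs,",
      format(x$n_positions, big.mark = ","), "positions at k =", x$k_index, "\n")
  invisible(x)
}

#' Look up one seed in a map index
#'
#' @param index A `map_index`.
#' @param seed A `k_index`-length DNA string.
#' @return A tibble `contig`, `pos` (0-based), `strand` of all occurrences
#'   (either strand) of the seed.
#' @export
lookup_seed <- function(index, seed) {
  hits <- cpp_lookup_seed(unname(index$contigs), index$k_index, seed)
  tibble(contig = names(index$contigs)[hits$contig], pos = hits$pos,
         strand = hits$strand)
}

#' Map read pairs against an assembly
#'
#' Each mate is placed by seed voting (the most-supported contig/diagonal/
#' strand) followed by ungapped verification; pair status follows the
#' concordant-pair convention: both mates on the same contig, opposite strands
#' in FR orientation, insert within the window. Ties are broken
#' deterministically (lowest contig, then leftmost, then '+').
#'
#' @param reads A `sample_reads` tibble (columns `pair_id`, `mate1`, `mate2`).
#' @param index A `map_index` from [build_map_index()].
#' @param params Mapper parameters from [map_params()].
#' @return A tibble, one row per pair: `pair_id`, `status` (one of
#'   `"concordant"`, `"discordant"`, `"mate1_only"`, `"mate2_only"`,
#'   `"unaligned"`), and per-mate `contig`, `start`, `strand`, `mismatches`.
#' @export
map_read_pairs <- function(reads, index, params = map_params()) {
  res <- cpp_map_pairs(unname(index$contigs), reads$mate1, reads$mate2,
                       index$k_index, params$min_seed_frac,
                       params$max_mismatch_frac,
                       params$insert_window[1], params$insert_window[2])
  lev <- c("concordant", "discordant", "mate1_only", "mate2_only", "unaligned")
  cn <- names(index$contigs)
  tibble(
    pair_id = reads$pair_id,
    status = lev[res$status],
    contig1 = cn[res$contig1], start1 = res$start1,
    strand1 = c("+", "-")[res$strand1 + 1L], mismatches1 = res$mismatch1,
    contig2 = cn[res$contig2], start2 = res$start2,
    strand2 = c("+", "-")[res$strand2 + 1L], mismatches2 = res$mismatch2
  )
}

#' @rdname map_read_pairs
#' @param pair A single-row `sample_reads` (or one-pair tibble).
#' @export
map_pair <- function(pair, index, params = map_params()) {
  map_read_pairs(pair[1, , drop = FALSE], index, params)
}

#' Partition a sample into concordant and unaligned read pools
#'
#' Mirrors the read-subtraction step: pairs aligning concordantly to the
#' assembly are "uninformative" and subtracted; all other pairs (discordant,
#' single-mate, unaligned — the `--un-conc-gz` convention) are retained in the
#' unaligned pool for re-assembly. Overall read alignment is the percentage of
#' mates (reads, not pairs) with at least one placement.
#'
#' @inheritParams map_read_pairs
#' @param keep_discordant Retain discordant pairs in the pool (default TRUE,
#'   the `--un-conc-gz` behaviour). Set FALSE to subtract them as well.
#' @return A `partition_result` list: `summary` (one-row tibble with per-status
#'   counts and `overall_alignment_pct`), `pool` (a `sample_reads` of retained
#'   pairs) and `alignments` (the per-pair table).
#' @export
partition_sample <- function(reads, index, params = map_params(),
                             keep_discordant = TRUE) {
  sample_id <- attr(reads, "sample_id") %||% "sample"
  if (nrow(reads) == 0) {
    warn(sprintf("sample %s is empty", sample_id))
    aln <- map_read_pairs(reads, index, params)
    summary <- tibble(sample_id = sample_id, pairs = 0L, concordant = 0L,
                      discordant = 0L, mate1_only = 0L, mate2_only = 0L,
                      unaligned = 0L, overall_alignment_pct = 0)
    return(structure(list(summary = summary, pool = reads, alignments = aln),
                     class = "partition_result"))
  }
  aln <- map_read_pairs(reads, index, params)
  subtracted <- aln$status == "concordant"
  if (!keep_discordant) subtracted <- subtracted | aln$status == "discordant"
  placed_mates <- sum(!is.na(aln$contig1)) + sum(!is.na(aln$contig2))
  counts <- table(factor(aln$status,
                         levels = c("concordant", "discordant", "mate1_only",
                                    "mate2_only", "unaligned")))
  summary <- tibble(
    sample_id = sample_id,
    pairs = nrow(reads),
    concordant = as.integer(counts["concordant"]),
    discordant = as.integer(counts["discordant"]),
    mate1_only = as.integer(counts["mate1_only"]),
    mate2_only = as.integer(counts["mate2_only"]),
    unaligned = as.integer(counts["unaligned"]),
    overall_alignment_pct = 100 * placed_mates / (2 * nrow(reads))
  )
  pool <- new_sample_reads(reads[!subtracted, , drop = FALSE], sample_id,
                           attr(reads, "read_len"))
  structure(list(summary = summary, pool = pool, alignments = aln),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Sample %s: %d pairs, %d concordant (subtracted), pool %d pairs, overall alignment %.2f%%\n",
    s$sample_id, s$pairs, s$concordant, nrow(x$pool),
    s$overall_alignment_pct))
  invisible(x)
}

contig_seqs <- function(assembly) {
  if (inherits(assembly, "assembly") || is.data.frame(assembly))
    return(setNames(assembly$sequence, assembly$contig_id))
  if (is.character(assembly)) {
    nm <- names(assembly) %||% sprintf("contig_%06d", seq_along(assembly))
    return(setNames(unname(assembly), nm))
  }
  if (methods::is(assembly, "DNAStringSet")) return(as_seq_chr(assembly))
  abort("expected an assembly tibble, character vector or DNAStringSet")
}
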