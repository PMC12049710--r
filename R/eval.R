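#' Align contigs to reference genomes
#'
#' A lightweight reference aligner for evaluation: exact 31-mer anchors are
#' grouped by (reference, strand, diagonal) into ungapped blocks, block ends
#' are extended while bases match exactly, mismatches are counted inside each
#' block, and a greedy longest-first selection keeps blocks non-overlapping on
#' the contig. Adequate for substitution-only divergence; there is no gapped
#' or split-base-level alignment.
#'
#' @param assembly An `assembly` tibble (or named character vector of contigs).
#' @param refs Reference genomes (named character vector or DNAStringSet).
#' @param k_anchor Anchor k-mer size in bp.
#' @param min_block Minimum block length to keep (bp).
#' @param max_anchor_gap Maximum distance between consecutive anchors merged
#'   into one block (bp).
#' @return A `contig_alignments` tibble, one row per block: `contig_id`,
#'   `contig_start`, `contig_end`, `ref`, `ref_start`, `ref_end` (all 0-based
#'   half-open), `strand`, `mismatches`. Contig and reference lengths travel
#'   as attributes.
#' @export
align_contigs <- function(assembly, refs, k_anchor = 31, min_block = 65,
                          max_anchor_gap = 1000) {
  contigs <- contig_seqs(assembly)
  seqs <- as_seq_chr(refs)
  if (length(contigs) == 0 || length(seqs) == 0)
    abort("assembly and references must be non-empty")
  df <- cpp_align_contigs(unname(contigs), unname(seqs),
                          as.integer(k_anchor), as.integer(min_block),
                          as.integer(max_anchor_gap))
  tb <- tibble(
    contig_id = names(contigs)[df$contig],
    contig_start = df$contig_start, contig_end = df$contig_end,
    ref = names(seqs)[df$ref],
    ref_start = df$ref_start, ref_end = df$ref_end,
    strand = df$strand, mismatches = df$mismatches
  )
  structure(tb,
            contig_lengths = setNames(nchar(contigs), names(contigs)),
            ref_lengths = setNames(nchar(seqs), names(seqs)),
            class = c("contig_alignments", class(tibble())))
}

#' Recovered genome fraction
#'
#' Percentage of reference bases covered by at least one aligned contig block.
#' A reference base counts once no matter how many blocks cover it (coverage
#' multiplicity is the duplication ratio's job).
#'
#' @param alignments Blocks from [align_contigs()].
#' @param refs The reference genomes the alignment was computed against.
#' @return Percent in `[0, 100]`.
#' @export
genome_fraction <- function(alignments, refs) {
  total <- sum(nchar(as_seq_chr(refs)))
  100 * covered_ref_bases(alignments) / total
}

#' Duplication ratio
#'
#' Total aligned contig bases divided by the number of reference bases covered
#' at least once; 1.0 for a single-copy perfect sub-assembly, > 1 when the
#' same reference sequence is assembled redundantly. `NA` when nothing aligns.
#'
#' @inheritParams genome_fraction
#' @return A ratio >= 1, or `NA_real_` when no block exists.
#' @export
duplication_ratio <- function(alignments, refs) {
  covered <- covered_ref_bases(alignments)
  if (covered == 0) return(NA_real_)
  sum(alignments$contig_end - alignments$contig_start) / covered
}

covered_ref_bases <- function(alignments) {
  if (nrow(alignments) == 0) return(0)
  ir <- IRanges::IRanges(start = alignments$ref_start + 1L,
                         end = alignments$ref_end)
  by_ref <- S4Vectors::split(ir, alignments$ref)
  sum(sum(IRanges::width(IRanges::reduce(by_ref))))
}

#' Count misassemblies from contig-to-reference blocks
#'
#' Adjacent blocks within a contig are compared: a switch of reference or
#' strand, or a positional inconsistency of at least `extensive_bp`, is an
#' extensive misassembly; an inconsistency inside `local_range` is a local
#' misassembly. The inconsistency is the absolute difference between the gap
#' implied on the reference and the gap on the contig. `misassembled_contig_length`
#' sums the lengths of contigs carrying at least one extensive misassembly
#' (each contig counted once).
#'
#' @param alignments Blocks from [align_contigs()].
#' @param extensive_bp Inconsistency threshold for an extensive misassembly.
#' @param local_range Inclusive inconsistency range counted as local.
#' @param contig_lengths Named contig lengths; defaults to the attribute
#'   attached by [align_contigs()].
#' @return A list: `misassemblies`, `local_misassemblies`,
#'   `misassembled_contig_length`.
#' @export
count_misassemblies <- function(alignments, extensive_bp = 1000,
                                local_range = c(50, 999),
                                contig_lengths = attr(alignments, "contig_lengths")) {
  if (nrow(alignments) < 2)
    return(list(misassemblies = 0L, local_misassemblies = 0L,
                misassembled_contig_length = 0))
  ext <- 0L
  loc <- 0L
  bad_contigs <- character(0)
  for (cid in unique(alignments$contig_id)) {
    b <- alignments[alignments$contig_id == cid, , drop = FALSE]
    b <- b[order(b$contig_start), , drop = FALSE]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1L)) {
      a <- b[i, ]
      z <- b[i + 1L, ]
      if (a$ref != z$ref || a$strand != z$strand) {
        ext <- ext + 1L
        bad_contigs <- c(bad_contigs, cid)
        next
      }
      cgap <- z$contig_start - a$contig_end
      rgap <- if (a$strand == "+") z$ref_start - a$ref_end
              else a$ref_start - z$ref_end
      inconsistency <- abs(rgap - cgap)
      if (inconsistency >= extensive_bp) {
        ext <- ext + 1L
        bad_contigs <- c(bad_contigs, cid)
      } else if (inconsistency >= local_range[1] &&
                 inconsistency <= local_range[2]) {
        loc <- loc + 1L
      }
    }
  }
  bad_len <- if (length(bad_contigs) > 0 && !is.null(contig_lengths)) {
    sum(contig_lengths[unique(bad_contigs)])
  } else 0
  list(misassemblies = ext, local_misassemblies = loc,
       misassembled_contig_length = unname(bad_len))
}

#' Mismatch rate of aligned contig bases
#'
#' @inheritParams count_misassemblies
#' @return Mismatches per 100 kbp of aligned contig sequence, or `NA_real_`
#'   when nothing aligns.
#' @export
mismatches_per_100kbp <- function(alignments) {
  aligned <- sum(alignments$contig_end - alignments$contig_start)
  if (aligned == 0) return(NA_real_)
  1e5 * sum(alignments$mismatches) / aligned
}

#' Assembly contiguity statistics
#'
#' `auN = sum(L_i^2) / sum(L_i)` (area under the Nx curve); N50 is the length
#' at which the cumulative length of contigs sorted descending first reaches
#' half the total.
#'
#' @param assembly An `assembly` tibble (or character vector of contigs).
#' @return A one-row tibble: `auN`, `N50`, `total_len_ge_50kbp`, `total_length`.
#' @export
contiguity_stats <- function(assembly) {
  lens <- if (is.data.frame(assembly)) assembly$length
          else nchar(contig_seqs(assembly))
  if (length(lens) == 0) {
    warn("empty assembly: contiguity statistics are zero")
    return(tibble(auN = 0, N50 = 0, total_len_ge_50kbp = 0, total_length = 0))
  }
  lens <- sort(as.numeric(lens), decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  tibble(auN = sum(lens^2) / total, N50 = n50,
         total_len_ge_50kbp = sum(lens[lens >= 50000]), total_length = total)
}

#' Reference-free evaluation by overall read alignment
#'
#' Maps every sample's pairs back to the assembly and reports the per-sample
#' overall read alignment (percentage of mates with at least one placement) —
#' the reference-free proxy for genome content recovery.
#'
#' @param readsets Named list of `sample_reads`.
#' @param assembly An `assembly` tibble.
#' @param params Mapper parameters ([map_params()]).
#' @return A tibble `sample_id`, `overall_alignment_pct`, with `mean` and `sd`
#'   attributes.
#' @export
read_alignment_eval <- function(readsets, assembly, params = map_params()) {
  if (nrow(assembly) == 0 || sum(nchar(contig_seqs(assembly)) >= params$k_index) == 0) {
    tb <- tibble(sample_id = names(readsets),
                 overall_alignment_pct = rep(0, length(readsets)))
    return(structure(tb, mean = 0, sd = stats::sd(tb$overall_alignment_pct)))
  }
  index <- build_map_index(assembly, params$k_index)
  tb <- bind_rows(lapply(readsets, function(r) {
    partition_sample(r, index, params)$summary[, c("sample_id",
                                                   "overall_alignment_pct")]
  }))
  structure(tb, mean = mean(tb$overall_alignment_pct),
            sd = stats::sd(tb$overall_alignment_pct))
}

#' Full evaluation report for one assembly
#'
#' The reference-based metric bundle (aligned length, genome fraction,
#' duplication ratio, misassembly counts, mismatch rate, contiguity) plus,
#' when read sets are supplied, the reference-free overall read alignment.
#'
#' @param assembly An `assembly` tibble.
#' @param refs Reference genomes.
#' @param readsets Optional named list of `sample_reads` for the
#'   reference-free metric.
#' @param params Mapper parameters for read alignment.
#' @param label Strategy label for the report row.
#' @return A one-row `eval_report` tibble.
#' @export
evaluate_assembly <- function(assembly, refs, readsets = NULL,
                              params = map_params(), label = "assembly") {
  ctg <- contiguity_stats(assembly)
  if (nrow(assembly) == 0) {
    aln_len <- 0; gf <- 0; dup <- NA_real_
    mis <- list(misassemblies = 0L, local_misassemblies = 0L,
                misassembled_contig_length = 0)
    mm <- NA_real_
  } else {
    blocks <- align_contigs(assembly, refs)
    aln_len <- sum(blocks$contig_end - blocks$contig_start)
    gf <- genome_fraction(blocks, refs)
    dup <- duplication_ratio(blocks, refs)
    mis <- count_misassemblies(blocks)
    mm <- mismatches_per_100kbp(blocks)
  }
  mean_aln <- NA_real_
  sd_aln <- NA_real_
  if (!is.null(readsets)) {
    ra <- read_alignment_eval(readsets, assembly, params)
    mean_aln <- attr(ra, "mean")
    sd_aln <- attr(ra, "sd")
  }
  tb <- tibble(
    label = label,
    n_contigs = nrow(assembly),
    total_length = ctg$total_length,
    aligned_length = aln_len,
    genome_fraction = gf,
    duplication_ratio = dup,
    misassemblies = mis$misassemblies,
    local_misassemblies = mis$local_misassemblies,
    misassembled_contig_length = mis$misassembled_contig_length,
    mismatches_per_100kbp = mm,
    auN = ctg$auN,
    N50 = ctg$N50,
    total_len_ge_50kbp = ctg$total_len_ge_50kbp,
    mean_read_alignment_pct = mean_aln,
    sd_read_alignment_pct = sd_aln
  )
  structure(tb, class = c("eval_report", class(tibble())))
}

#' Fit overall read alignment against log genome fraction
#'
#' Across strategies, mean overall read alignment is approximately linear in
#' the log of mean recovered genome fraction (both tracking the cumulative
#' abundance curve of the community).
#'
#' @param comparison A `strategy_comparison` (or any tibble with
#'   `mean_read_alignment_pct` and `genome_fraction` columns).
#' @return An `lm` fit of `mean_read_alignment_pct ~ log(genome_fraction)`.
#' @export
fit_alignment_model <- function(comparison) {
  lm(mean_read_alignment_pct ~ log(genome_fraction), data = comparison)
}
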