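#' Minimum sequencing depth for a per-genome read target
#'
#' In an uneven community, the rarest organism dictates total depth: to obtain
#' at least `min_reads_per_genome` reads from every organism when read share
#' equals relative abundance, the sample must be sequenced to
#' `ceiling(min_reads_per_genome / min(abundances))` reads. For a 90/5/5
#' community and a 10,000-read target this is 200,000 reads, of which most are
#' redundant copies of the dominant genome.
#'
#' @param abundances Relative abundances, all > 0, summing to 1 (within 1e-6).
#' @param min_reads_per_genome Required reads per genome (>= 1).
#' @return The required total read count (a single number).
#' @examples
#' required_depth(c(0.9, 0.05, 0.05), 10000)  # 200000
#' required_depth(rep(1 / 3, 3), 10000)       # 30000
#' @export
required_depth <- function(abundances, min_reads_per_genome) {
  check_abundances(abundances)
  stopifnot(min_reads_per_genome >= 1)
  ceiling(min_reads_per_genome / min(abundances))
}

#' Expected per-organism read counts at a given depth
#'
#' Element-wise `depth * abundance`, rounded to integers by largest-remainder
#' apportionment so the counts always sum exactly to `depth` (remainder ties go
#' to the later entry).
#'
#' @param abundances Relative abundances summing to 1.
#' @param depth Total read count (>= 0).
#' @return Integer-valued vector of expected read counts, summing to `depth`.
#' @examples
#' expected_reads(c(0.9, 0.05, 0.05), 200000)  # 180000 10000 10000
#' @export
expected_reads <- function(abundances, depth) {
  check_abundances(abundances, allow_zero = TRUE)
  stopifnot(depth >= 0)
  raw <- depth * abundances / sum(abundances)
  base <- floor(raw)
  rem <- raw - base
  deficit <- round(depth - sum(base))
  if (deficit > 0) {
    give <- order(-rem, -seq_along(rem))[seq_len(deficit)]
    base[give] <- base[give] + 1
  }
  base
}

#' Redundant-read excess of an uneven community
#'
#' The depth required to reach `min_reads_per_genome` for the rarest organism
#' exceeds the information-minimal `n_taxa * min_reads_per_genome`; the excess
#' is redundant sequencing that costs compute without adding assembly
#' information.
#'
#' @inheritParams required_depth
#' @return A list with `excess_reads` (required depth minus
#'   `n_taxa * min_reads_per_genome`) and `redundant_fraction`
#'   (`excess_reads / required depth`, in `[0, 1)`; 0 iff the community is
#'   exactly uniform).
#' @examples
#' excess_reads(c(0.9, 0.05, 0.05), 10000)  # 170000 excess, 85% redundant
#' @export
excess_reads <- function(abundances, min_reads_per_genome) {
  d <- required_depth(abundances, min_reads_per_genome)
  ex <- d - length(abundances) * min_reads_per_genome
  list(excess_reads = ex, redundant_fraction = ex / d)
}

#' Full depth plan for a community
#'
#' Bundles [required_depth()], [expected_reads()] and [excess_reads()] into one
#' report. With `genome_lengths`, read share is taken proportional to
#' abundance x length (the shotgun expectation) instead of abundance alone.
#'
#' @inheritParams required_depth
#' @param genome_lengths Optional genome lengths (bp), one per taxon.
#' @param taxa Optional taxon names.
#' @return A `depth_plan` object; `tidy()` gives the per-organism table,
#'   `glance()` the scalars.
#' @export
depth_plan <- function(abundances, min_reads_per_genome,
                       genome_lengths = NULL, taxa = NULL) {
  check_abundances(abundances)
  share <- abundances
  if (!is.null(genome_lengths)) {
    stopifnot(length(genome_lengths) == length(abundances),
              all(genome_lengths > 0))
    share <- abundances * genome_lengths
    share <- share / sum(share)
  }
  d <- ceiling(min_reads_per_genome / min(share))
  per <- expected_reads(share, d)
  taxa <- taxa %||% sprintf("taxon%02d", seq_along(abundances))
  ex <- d - length(share) * min_reads_per_genome
  structure(
    list(
      per_organism = tibble(taxon = taxa, abundance = abundances,
                            read_share = share, expected_reads = per),
      required_depth = d,
      min_reads_per_genome = min_reads_per_genome,
      excess_reads = ex,
      redundant_fraction = ex / d
    ),
    class = "depth_plan"
  )
}

#' @export
print.depth_plan <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Depth plan:", fmt(x$required_depth),
      "reads required for >=", fmt(x$min_reads_per_genome),
      "reads/genome\n")
  cat("Redundant excess:", fmt(x$excess_reads),
      sprintf("reads (%.1f%%)\n", 100 * x$redundant_fraction))
  print(x$per_organism)
  invisible(x)
}

#' @export
tidy.depth_plan <- function(x, ...) x$per_organism

#' @export
glance.depth_plan <- function(x, ...) {
  tibble(required_depth = x$required_depth,
         min_reads_per_genome = x$min_reads_per_genome,
         excess_reads = x$excess_reads,
         redundant_fraction = x$redundant_fraction)
}

check_abundances <- function(abundances, allow_zero = FALSE) {
  if (length(abundances) < 1) abort("need at least one abundance")
  if (allow_zero) {
    if (any(abundances < 0)) abort("abundances must be non-negative")
  } else if (any(abundances <= 0)) {
    abort("all abundances must be > 0 (a zero-abundance organism can never reach the read minimum)")
  }
  if (abs(sum(abundances) - 1) > 1e-6)
    abort("abundances must sum to 1")
  invisible(TRUE)
}
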