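#' Generate a reference set of random genomes
#'
#' Draws `n_genomes` i.i.d. random DNA sequences (alphabet A/C/G/T, no N) to act
#' as the ground-truth community for simulation and as the reference set for
#' assembly evaluation. Lengths are drawn uniformly from `length_range`; base
#' composition follows the target GC fraction. No emitted genome is a substring
#' of another (collisions are regenerated, though at these lengths they are
#' astronomically unlikely).
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param length_range Length interval in bp, `c(min, max)`; both >= 1.
#' @param gc Target GC fraction, strictly inside (0, 1).
#' @param seed Integer seed; the same call with the same seed is byte-identical.
#' @return A named [Biostrings::DNAStringSet] with ids `g001`, `g002`, ...
#' @examples
#' refs <- generate_genomes(3, c(1000, 2000), gc = 0.5, seed = 1)
#' Biostrings::width(refs)
#' @export
generate_genomes <- function(n_genomes, length_range = c(5000, 20000),
                             gc = 0.5, seed = 1) {
  stopifnot(n_genomes >= 1)
  if (length(length_range) != 2 || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    abort("length_range must be c(min, max) with 1 <= min <= max")
  }
  if (gc <= 0 || gc >= 1) abort("gc must be strictly inside (0, 1)")
  set.seed(seed %% .Machine$integer.max)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n_genomes,
                     replace = TRUE) + length_range[1] - 1L
  seqs <- character(n_genomes)
  stream <- 0L
  for (i in seq_len(n_genomes)) {
    repeat {
      stream <- stream + 1L
      s <- cpp_random_sequence(lens[i], gc, derive_seed(seed, 7700L + stream))
      if (i == 1L || !any(vapply(seqs[seq_len(i - 1L)], function(prev) {
        grepl(s, prev, fixed = TRUE) || grepl(prev, s, fixed = TRUE)
      }, logical(1)))) break
    }
    seqs[i] <- s
  }
  names(seqs) <- sprintf("g%03d", seq_len(n_genomes))
  Biostrings::DNAStringSet(seqs)
}

#' Write / read a reference set as FASTA
#'
#' Plain FASTA with 80-column wrapping, as produced for `refs.fa`.
#'
#' @param refs A named [Biostrings::DNAStringSet].
#' @param path Output (or input) FASTA path.
#' @return `write_references()` returns `path` invisibly; `read_references()`
#'   returns a [Biostrings::DNAStringSet].
#' @export
write_references <- function(refs, path) {
  Biostrings::writeXStringSet(as_dna(refs), path, width = 80L)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# Coerce named character vectors / DNAStringSet to DNAStringSet.
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  abort("expected a DNAStringSet or a named character vector of sequences")
}

# Character view of sequences, preserving names.
as_seq_chr <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    abort("expected a DNAStringSet or a character vector")
  }
}

# Derive a bounded sub-seed from the master seed: independent streams for
# samples/genomes without perturbing earlier streams when more are added.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483647
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
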