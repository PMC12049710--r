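#' Canonical k-mer spectrum of a read set
#'
#' Counts the canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) of both mates of every pair, then drops k-mers seen
#' fewer than `min_count` times. This is the node set of the de Bruijn graph
#' the assembler walks.
#'
#' @param reads A `sample_reads` tibble, a list of them, or a character vector
#'   of sequences.
#' @param k Odd k-mer size in bp (<= 31).
#' @param min_count Minimum k-mer multiplicity to keep (default 2 drops
#'   singleton error k-mers).
#' @return A tibble `kmer`, `count`, sorted by k-mer.
#' @examples
#' kmer_graph("ACGTGCAGG", k = 5, min_count = 1)
#' @export
kmer_graph <- function(reads, k = 31, min_count = 2) {
  seqs <- collect_mates(reads)
  res <- cpp_kmer_counts(seqs, as.integer(k), as.integer(min_count))
  if (res$n_reads_used == 0)
    abort(if (length(seqs) == 0) "no reads provided"
          else sprintf("all reads are shorter than k = %d", k))
  if (res$n_reads_short > 0)
    warn(sprintf("%d reads shorter than k = %d were skipped",
                 res$n_reads_short, k))
  tibble(kmer = as.character(res$kmer), count = as.integer(res$count))
}

#' Assemble reads into unitigs
#'
#' A single-k de Bruijn graph assembler: canonical k-mers with multiplicity of
#' at least `min_count` form the graph; contigs are its maximal non-branching paths
#' (unitigs). There is no bubble popping or tip clipping — any branch ends a
#' unitig — so the output is exactly characterised by the graph and is
#' byte-identical across reruns. Each unitig is emitted in its
#' lexicographically smaller orientation; contigs are ordered by length
#' (descending) then sequence, and named `contig_000001`, ...
#'
#' The backend contract is: a list of read sets in, a contig table out. The
#' `"megahit"` backend shells out to an external MEGAHIT binary honouring the
#' same contract (multi-k, non-deterministic; not used by any internal test);
#' the default `"internal"` backend is the bundled assembler.
#'
#' @inheritParams kmer_graph
#' @param min_count Minimum k-mer multiplicity, or `"auto"` to choose the
#'   cutoff from the k-mer count spectrum (see [choose_min_count()]). The
#'   fixed default of 2 drops singleton error k-mers and suits moderate
#'   coverage; deeply sequenced data accumulates recurrent error k-mers whose
#'   branches fragment unitigs, which the spectrum-based cutoff removes.
#' @param min_contig_len Minimum contig length to report (bp).
#' @param backend `"internal"` (bundled) or `"megahit"` (external binary).
#' @return An `assembly`: a tibble `contig_id`, `length`, `sequence`, with the
#'   assembly parameters attached as attributes.
#' @examples
#' asm <- assemble_reads(c("ACGTG", "GTGCA"), k = 3, min_count = 1,
#'                       min_contig_len = 5)
#' asm$sequence
#' @export
assemble_reads <- function(reads, k = 31, min_count = 2, min_contig_len = 200,
                           backend = c("internal", "megahit")) {
  backend <- match.arg(backend)
  if (backend == "megahit")
    return(assemble_megahit(reads, min_contig_len))
  if (k %% 2 == 0) abort("k must be odd")
  seqs <- collect_mates(reads)
  if (identical(min_count, "auto")) min_count <- choose_min_count(seqs, k)
  res <- cpp_assemble(seqs, as.integer(k), as.integer(min_count),
                      as.integer(min_contig_len))
  if (res$n_reads_used == 0)
    abort(if (length(seqs) == 0) "no reads provided"
          else sprintf("all reads are shorter than k = %d", k))
  if (res$n_reads_short > 0)
    warn(sprintf("%d reads shorter than k = %d were skipped",
                 res$n_reads_short, k))
  contigs <- as.character(res$contigs)
  new_assembly(contigs, k = k, min_count = min_count,
               min_contig_len = min_contig_len,
               source = sources_of(reads))
}

new_assembly <- function(contigs, k, min_count, min_contig_len, source = NULL) {
  tb <- tibble(
    contig_id = sprintf("contig_%06d", seq_along(contigs)),
    length = nchar(contigs),
    sequence = contigs
  )
  structure(tb,
            params = list(k = k, min_count = min_count,
                          min_contig_len = min_contig_len),
            source = source,
            class = c("assembly", class(tibble())))
}

#' Write / read an assembly as FASTA
#'
#' `write_assembly_fasta()` also writes `assembly_info.tsv` (contig_id, length)
#' next to the FASTA when `info = TRUE`.
#'
#' @param assembly An `assembly` tibble.
#' @param path FASTA path.
#' @param info Also write `assembly_info.tsv` alongside.
#' @export
write_assembly_fasta <- function(assembly, path, info = FALSE) {
  seqs <- Biostrings::DNAStringSet(setNames(assembly$sequence,
                                            assembly$contig_id))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  if (info) {
    readr::write_tsv(assembly[, c("contig_id", "length")],
                     file.path(dirname(path), "assembly_info.tsv"))
  }
  invisible(path)
}

#' @rdname write_assembly_fasta
#' @export
read_assembly_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tb <- tibble(contig_id = sub("\\s.*$", "", names(seqs)),
               length = Biostrings::width(seqs),
               sequence = unname(as.character(seqs)))
  structure(tb, params = list(k = NA, min_count = NA, min_contig_len = NA),
            class = c("assembly", class(tibble())))
}

# External MEGAHIT adapter: same contract (FASTQ pairs in, contig FASTA out).
# Requires a megahit binary on PATH; excluded from the unit-test surface.
assemble_megahit <- function(reads, min_contig_len) {
  if (Sys.which("megahit") == "")
    abort("the 'megahit' backend requires a megahit binary on PATH")
  readsets <- if (inherits(reads, "sample_reads")) list(reads) else reads
  work <- tempfile("megahit_in_")
  dir.create(work)
  paths <- lapply(seq_along(readsets), function(i)
    write_sample_fastq(readsets[[i]], work, sprintf("s%03d", i)))
  r1 <- paste(vapply(paths, `[`, "", 1L), collapse = ",")
  r2 <- paste(vapply(paths, `[`, "", 2L), collapse = ",")
  out <- tempfile("megahit_out_")
  status <- system2("megahit",
                    c("-1", r1, "-2", r2, "-o", out,
                      "--min-contig-len", min_contig_len))
  if (status != 0) abort("megahit exited with a non-zero status")
  read_assembly_fasta(file.path(out, "final.contigs.fa"))
}

# Gather mate sequences from the accepted read-input shapes.
collect_mates <- function(reads) {
  if (inherits(reads, "sample_reads") || is.data.frame(reads))
    return(c(reads$mate1, reads$mate2))
  if (is.list(reads))
    return(unlist(lapply(reads, collect_mates), use.names = FALSE))
  if (is.character(reads)) return(unname(reads))
  abort("reads must be sample_reads, a list of them, or a character vector")
}

sources_of <- function(reads) {
  if (inherits(reads, "sample_reads")) return(attr(reads, "sample_id"))
  if (is.list(reads) && !is.data.frame(reads))
    return(unlist(lapply(reads, sources_of), use.names = FALSE))
  NULL
}

#' Choose a k-mer count cutoff from the count spectrum
#'
#' The histogram of canonical k-mer multiplicities of shotgun reads typically
#' shows a monotone error tail at low counts followed by genuine coverage
#' peaks. The cutoff is the first count at which the histogram stops
#' decreasing (the valley after the error tail), the classical
#' coverage-spectrum rule. If there are no singleton k-mers the data carries
#' no error tail and the cutoff falls back to 2.
#'
#' @param reads Read input as for [kmer_graph()].
#' @param k K-mer size in bp.
#' @param max_count Histogram cap.
#' @return An integer cutoff: keep k-mers with count >= this value.
#' @export
choose_min_count <- function(reads, k = 31, max_count = 100) {
  seqs <- collect_mates(reads)
  h <- cpp_kmer_histogram(seqs, as.integer(k), as.integer(max_count))
  if (h[1] == 0) return(2L)
  for (c in 2:(max_count - 1)) {
    if (h[c] <= h[c + 1]) return(as.integer(c))
  }
  2L
}
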