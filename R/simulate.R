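#' Simulate paired-end shotgun reads for every sample of a community
#'
#' For each sample, read-pair origins are drawn multinomially with probability
#' proportional to abundance x genome length (shotgun read share scales with
#' genome size; set `weighted = FALSE` to equate read share with organismal
#' abundance instead). Fragments are placed uniformly along the origin genome,
#' fragment length is Gaussian `insert`, the pair is emitted in FR orientation
#' from a uniformly random strand, and substitution errors are applied i.i.d.
#' per base. Quality strings are a constant 'I' (Phred 40); the error model is
#' substitution-only by design.
#'
#' Per-sample random streams are derived from the master seed by fixed offsets,
#' so adding samples never perturbs the reads of earlier samples.
#'
#' @param profile A `community_profile` (see [assign_abundances()]).
#' @param refs Reference genomes the profile indexes into.
#' @param depth Read pairs per sample.
#' @param read_len Read length in bp (both mates).
#' @param insert_mean,insert_sd Fragment (insert) length mean and sd in bp. A
#'   warning is issued when `insert_mean < 2 * read_len` (overlapping mates).
#' @param error_rate Per-base substitution probability.
#' @param weighted Length-weight the origin probabilities (default TRUE).
#' @param seed Master integer seed.
#' @return A named list of `sample_reads` tibbles, one per sample, each with
#'   columns `pair_id`, `mate1`, `mate2`, `origin`, `start`, `strand` (truth
#'   columns record the fragment's forward-strand 0-based start).
#' @examples
#' refs <- generate_genomes(2, c(2000, 3000), seed = 1)
#' prof <- assign_abundances(refs, 2, core_fraction = 1, seed = 1)
#' reads <- simulate_reads(prof, refs, depth = 50, seed = 1)
#' reads[[1]]
#' @export
simulate_reads <- function(profile, refs, depth, read_len = 100,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0.002, weighted = TRUE, seed = 1) {
  stopifnot(depth >= 1, read_len >= 1)
  if (insert_mean < 2 * read_len)
    warn("insert_mean < 2 * read_len: mates will overlap")
  seqs <- as_seq_chr(refs)
  mat <- abundance_matrix(profile)
  if (!all(colnames(mat) %in% names(seqs)))
    abort("profile taxa missing from the reference set")
  seqs <- seqs[colnames(mat)]
  lens <- nchar(seqs)
  samples <- rownames(mat)

  out <- vector("list", length(samples))
  names(out) <- samples
  for (i in seq_along(samples)) {
    probs <- mat[i, ]
    if (weighted) probs <- probs * lens
    sim <- cpp_simulate_sample(unname(seqs), unname(probs), as.integer(depth),
                               as.integer(read_len), insert_mean, insert_sd,
                               error_rate, derive_seed(seed, i))
    tb <- tibble(
      pair_id = sprintf("%s_p%06d", samples[i], seq_len(depth)),
      mate1 = as.character(sim$mate1),
      mate2 = as.character(sim$mate2),
      origin = colnames(mat)[sim$origin],
      start = sim$start,
      strand = as.character(sim$strand)
    )
    out[[i]] <- new_sample_reads(tb, samples[i], read_len)
  }
  out
}

new_sample_reads <- function(tb, sample_id, read_len) {
  structure(tb, sample_id = sample_id, read_len = read_len,
            class = c("sample_reads", class(tibble())))
}

#' Deterministic deep-tiling read pairs from one genome
#'
#' Emits an error-free FR pair for every `step`-th fragment start position,
#' `copies` times over. Unlike random fragment sampling, tiling covers every
#' k-mer of the genome (including the termini) with multiplicity >= `copies`,
#' which makes it the right fixture for exact-reconstruction oracles.
#'
#' @param genome A single sequence (character or DNAStringSet of length 1).
#' @param read_len Read length in bp.
#' @param insert Fixed fragment length in bp (>= read_len, <= genome length).
#' @param step Distance between consecutive fragment starts.
#' @param copies Number of copies of each pair.
#' @return A `sample_reads` tibble (truth columns filled, strand "+").
#' @export
tile_read_pairs <- function(genome, read_len = 100, insert = 300,
                            step = 1, copies = 2) {
  g <- as_seq_chr(genome)[[1]]
  glen <- nchar(g)
  stopifnot(insert >= read_len, insert <= glen, step >= 1, copies >= 1)
  starts <- rep(seq(0L, glen - insert, by = step), each = copies)
  m1 <- substring(g, starts + 1L, starts + read_len)
  m2 <- revcomp_chr(substring(g, starts + insert - read_len + 1L,
                              starts + insert))
  tb <- tibble(
    pair_id = sprintf("tile_p%06d", seq_along(starts)),
    mate1 = m1, mate2 = m2,
    origin = names(as_seq_chr(genome))[1] %||% "g001",
    start = starts, strand = "+"
  )
  new_sample_reads(tb, "tile", read_len)
}

#' Write / read one sample's pairs as gzipped FASTQ
#'
#' Standard 4-line FASTQ records; mate ids carry `/1` and `/2` suffixes and the
#' constant quality string 'I'. `read_sample_fastq()` accepts plain or gzipped
#' files and pairs records positionally.
#'
#' @param reads A `sample_reads` tibble.
#' @param dir Output directory (created if needed).
#' @param sample_id Basename for `<sample>_R1.fq.gz` / `<sample>_R2.fq.gz`;
#'   defaults to the read set's own sample id.
#' @param gz Compress output (default TRUE).
#' @return Invisibly, the two file paths.
#' @export
write_sample_fastq <- function(reads, dir, sample_id = NULL, gz = TRUE) {
  sample_id <- sample_id %||% attr(reads, "sample_id")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gz) ".fq.gz" else ".fq"
  p1 <- file.path(dir, paste0(sample_id, "_R1", ext))
  p2 <- file.path(dir, paste0(sample_id, "_R2", ext))
  write_fastq_one(reads$mate1, paste0(reads$pair_id, "/1"), p1, gz)
  write_fastq_one(reads$mate2, paste0(reads$pair_id, "/2"), p2, gz)
  invisible(c(p1, p2))
}

write_fastq_one <- function(seqs, ids, path, gz) {
  qual <- strrep("I", nchar(seqs))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", qual)
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(rec, con)
}

#' @rdname write_sample_fastq
#' @param r1,r2 Paths to the R1 and R2 FASTQ files.
#' @export
read_sample_fastq <- function(r1, r2, sample_id = NULL) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) abort("R1 and R2 differ in record count")
  ids <- sub("/1$", "", sub("\\s.*$", "", names(s1)))
  sample_id <- sample_id %||% sub("_R1.*$", "", basename(r1))
  tb <- tibble(pair_id = unname(ids), mate1 = unname(as.character(s1)),
               mate2 = unname(as.character(s2)),
               origin = NA_character_, start = NA_integer_,
               strand = NA_character_)
  new_sample_reads(tb, sample_id, max(nchar(tb$mate1), 0L))
}

#' Write simulation ground truth as gzipped TSV
#'
#' One row per pair: `pair_id`, `sample_id`, `genome_id`, `start` (0-based,
#' forward strand), `strand`.
#'
#' @param readsets Named list of `sample_reads` (with truth columns).
#' @param path Output path (should end in `.tsv.gz`).
#' @export
write_truth_tsv <- function(readsets, path) {
  tb <- bind_rows(lapply(readsets, function(r) {
    tibble(pair_id = r$pair_id, sample_id = attr(r, "sample_id"),
           genome_id = r$origin, start = r$start, strand = r$strand)
  }))
  readr::write_tsv(tb, path)
  invisible(path)
}
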