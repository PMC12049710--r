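# Independent brute-force oracles, kept free of the package's C++ paths.

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

kmers_of <- function(seq, k) {
  if (nchar(seq) < k) return(character(0))
  substring(seq, seq_len(nchar(seq) - k + 1L), k:nchar(seq))
}

canon_chr <- function(kmers) pmin(kmers, rc_chr(kmers))

# Brute-force canonical k-mer counting.
brute_kmer_counts <- function(reads, k, min_count = 1) {
  all <- unlist(lapply(reads[nchar(reads) >= k], kmers_of, k = k))
  tab <- table(canon_chr(all))
  tab <- tab[tab >= min_count]
  tibble::tibble(kmer = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(kmer)
}

# Brute-force node-disjoint canonical unitigs: maximal non-branching paths of
# the canonical de Bruijn graph, each canonical k-mer used exactly once.
brute_unitigs <- function(reads, k, min_count = 1, min_contig_len = 0) {
  nodes <- brute_kmer_counts(reads, k, min_count)$kmer
  node_set <- new.env(parent = emptyenv())
  for (n in nodes) assign(n, TRUE, envir = node_set)
  has_node <- function(x) exists(pmin(x, rc_chr(x)), envir = node_set)

  succs <- function(seq) {  # oriented successors of an oriented k-mer string
    nxt <- paste0(substring(seq, 2), c("A", "C", "G", "T"))
    nxt[vapply(nxt, has_node, TRUE)]
  }
  n_preds <- function(seq) length(succs(rc_chr(seq)))

  visited <- new.env(parent = emptyenv())
  seen <- function(x) exists(pmin(x, rc_chr(x)), envir = visited)
  mark <- function(x) assign(pmin(x, rc_chr(x)), TRUE, envir = visited)

  walk <- function(cur) {
    path <- character(0)
    repeat {
      s <- succs(cur)
      if (length(s) != 1) break
      if (seen(s)) break
      if (n_preds(s) != 1) break
      mark(s)
      path <- c(path, s)
      cur <- s
    }
    path
  }

  contigs <- character(0)
  for (start in nodes) {  # nodes are sorted: deterministic start order
    if (seen(start)) next
    mark(start)
    right <- walk(start)
    left <- walk(rc_chr(start))
    path <- c(rev(rc_chr(left)), start, right)
    seq <- paste0(path[1],
                  paste(substring(path[-1], k, k), collapse = ""))
    if (nchar(seq) < min_contig_len) next
    contigs <- c(contigs, min(seq, rc_chr(seq)))
  }
  contigs[order(-nchar(contigs), contigs)]
}

# Brute-force per-base reference coverage from alignment blocks.
brute_coverage_metrics <- function(blocks, refs) {
  seqs <- if (methods::is(refs, "DNAStringSet")) {
    stats::setNames(as.character(refs), names(refs))
  } else refs
  covered <- 0
  for (g in names(seqs)) {
    hit <- logical(nchar(seqs[[g]]))
    b <- blocks[blocks$ref == g, , drop = FALSE]
    if (nrow(b) > 0) {
      for (i in seq_len(nrow(b))) {
        hit[(b$ref_start[i] + 1):b$ref_end[i]] <- TRUE
      }
    }
    covered <- covered + sum(hit)
  }
  aligned_contig_bases <- sum(blocks$contig_end - blocks$contig_start)
  list(
    genome_fraction = 100 * covered / sum(nchar(seqs)),
    duplication_ratio = if (covered == 0) NA_real_
                        else aligned_contig_bases / covered
  )
}

# A perfect single-copy assembly: the references themselves as contigs.
perfect_assembly <- function(refs) {
  seqs <- if (methods::is(refs, "DNAStringSet")) {
    stats::setNames(as.character(refs), names(refs))
  } else refs
  if (is.null(names(seqs))) names(seqs) <- character(length(seqs))
  structure(
    tibble::tibble(contig_id = names(seqs), length = nchar(seqs),
                   sequence = unname(seqs)),
    params = list(k = NA, min_count = NA, min_contig_len = NA),
    class = c("assembly", class(tibble::tibble())))
}

# Small in-code assembly constructor for fixtures.
fixture_assembly <- function(seqs) perfect_assembly(seqs)
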