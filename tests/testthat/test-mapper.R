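make_contig_reads <- function(contig, starts, read_len = 100, insert = 300) {
  tb <- tibble::tibble(
    pair_id = sprintf("p%04d", seq_along(starts)),
    mate1 = substring(contig, starts + 1, starts + read_len),
    mate2 = rc_chr(substring(contig, starts + insert - read_len + 1,
                             starts + insert)),
    origin = "c", start = starts, strand = "+"
  )
  seqcoasm:::new_sample_reads(tb, "fix", read_len)
}

test_that("the seed index counts and locates positions correctly", {
  contig <- as.character(generate_genomes(1, c(500, 500), seed = 31)[[1]])
  asm <- fixture_assembly(c(c1 = contig))
  idx <- build_map_index(asm, 31)
  expect_equal(idx$n_positions, 500 - 30)

  hit <- lookup_seed(idx, substr(contig, 1, 31))
  expect_identical(hit$contig, "c1")
  expect_identical(hit$pos, 0L)
  expect_identical(hit$strand, "+")

  # a contig plus its reverse complement: every seed hits both
  both <- build_map_index(fixture_assembly(c(c1 = contig,
                                             c2 = rc_chr(contig))), 31)
  hits2 <- lookup_seed(both, substr(contig, 100, 130))
  expect_gte(nrow(hits2), 2)

  expect_error(build_map_index(fixture_assembly(character(0))), "empty")
  expect_warning(build_map_index(fixture_assembly(c(a = contig, b = "ACGT")), 31),
                 "skipped")
})

test_that("pairs cut from a contig map concordantly; foreign pairs do not", {
  contig <- as.character(generate_genomes(1, c(2000, 2000), seed = 32)[[1]])
  idx <- build_map_index(fixture_assembly(c(c1 = contig)))
  reads <- make_contig_reads(contig, c(0L, 400L, 1500L))
  aln <- map_read_pairs(reads, idx)
  expect_true(all(aln$status == "concordant"))
  expect_identical(aln$start1, c(0L, 400L, 1500L))
  expect_true(all(aln$mismatches1 == 0))

  # unrelated random mates find no placement
  other <- as.character(generate_genomes(1, c(5000, 5000), seed = 33)[[1]])
  stray <- make_contig_reads(other, c(10L, 900L))
  expect_true(all(map_read_pairs(stray, idx)$status == "unaligned"))
})

test_that("mates on different contigs are discordant", {
  gs <- generate_genomes(2, c(1500, 1500), seed = 34)
  a <- as.character(gs[[1]])
  b <- as.character(gs[[2]])
  idx <- build_map_index(fixture_assembly(c(cA = a, cB = b)))
  pair <- tibble::tibble(
    pair_id = "x1",
    mate1 = substr(a, 101, 200),
    mate2 = rc_chr(substr(b, 501, 600)),
    origin = NA, start = NA, strand = NA
  )
  res <- map_pair(seqcoasm:::new_sample_reads(pair, "fix", 100), idx)
  expect_identical(res$status, "discordant")
  expect_identical(res$contig1, "cA")
  expect_identical(res$contig2, "cB")

  # same contig but out of the insert window is also discordant
  far <- tibble::tibble(pair_id = "x2",
                        mate1 = substr(a, 1, 100),
                        mate2 = rc_chr(substr(a, 1301, 1400)),
                        origin = NA, start = NA, strand = NA)
  expect_identical(
    map_pair(seqcoasm:::new_sample_reads(far, "fix", 100), idx)$status,
    "discordant")
})

test_that("partitioning mirrors concordant-only subtraction", {
  contig <- as.character(generate_genomes(1, c(3000, 3000), seed = 35)[[1]])
  idx <- build_map_index(fixture_assembly(c(c1 = contig)))

  own <- make_contig_reads(contig, seq(0L, 2000L, by = 250L))
  p <- partition_sample(own, idx)
  expect_identical(nrow(p$pool), 0L)
  expect_equal(p$summary$overall_alignment_pct, 100)

  # one concordant + one fully unaligned pair -> pool of 1, 50% alignment
  stray <- as.character(generate_genomes(1, c(2000, 2000), seed = 36)[[1]])
  mixed <- dplyr::bind_rows(make_contig_reads(contig, 100L),
                            make_contig_reads(stray, 700L))
  mixed <- seqcoasm:::new_sample_reads(mixed, "mix", 100)
  pm <- partition_sample(mixed, idx)
  expect_identical(nrow(pm$pool), 1L)
  expect_equal(pm$summary$overall_alignment_pct, 50)

  # unrelated index -> everything pooled at 0%
  p0 <- partition_sample(own, build_map_index(fixture_assembly(c(x = stray))))
  expect_identical(nrow(p0$pool), nrow(own))
  expect_equal(p0$summary$overall_alignment_pct, 0)

  empty <- seqcoasm:::new_sample_reads(own[0, ], "none", 100)
  expect_warning(pe <- partition_sample(empty, idx), "empty")
  expect_equal(pe$summary$overall_alignment_pct, 0)
})

test_that("partitioning neither loses nor duplicates pairs, and is idempotent", {
  refs <- generate_genomes(3, c(3000, 6000), seed = 37)
  prof <- assign_abundances(refs, 1, core_fraction = 1, seed = 37)
  reads <- simulate_reads(prof, refs, depth = 2000, seed = 38)[[1]]
  idx <- build_map_index(perfect_assembly(refs[1:2]))
  p <- partition_sample(reads, idx)

  expect_identical(p$summary$concordant + nrow(p$pool), nrow(reads))
  expect_identical(sort(c(p$pool$pair_id,
                          p$alignments$pair_id[p$alignments$status == "concordant"])),
                   sort(reads$pair_id))

  # subtraction soundness: the pool re-maps with zero concordant pairs
  p2 <- partition_sample(p$pool, idx)
  expect_identical(p2$summary$concordant, 0L)
  expect_identical(nrow(p2$pool), nrow(p$pool))
})

test_that("error-free pairs from assembled genomes are nearly all concordant", {
  refs <- generate_genomes(2, c(4000, 4000), seed = 39)
  prof <- assign_abundances(refs, 1, core_fraction = 1, seed = 39)
  reads <- simulate_reads(prof, refs, depth = 5000, error_rate = 0, seed = 40)[[1]]
  p <- partition_sample(reads, build_map_index(perfect_assembly(refs)))
  expect_gte(p$summary$concordant / nrow(reads), 0.99)
})

test_that("overall alignment grows with reference content", {
  refs <- generate_genomes(4, c(3000, 5000), seed = 41)
  prof <- assign_abundances(refs, 2, core_fraction = 1, seed = 41)
  reads <- simulate_reads(prof, refs, depth = 3000, seed = 42)
  full <- read_alignment_eval(reads, perfect_assembly(refs))
  part <- read_alignment_eval(reads, perfect_assembly(refs[1:2]))
  expect_true(all(full$overall_alignment_pct >= part$overall_alignment_pct))
})
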