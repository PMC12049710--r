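ref_pair <- function(seed = 51, len = 6000) {
  generate_genomes(2, c(len, len), seed = seed)
}

test_that("contig-to-reference blocks capture identity, strand and chimeras", {
  refs <- ref_pair()
  r1 <- as.character(refs[[1]])
  r2 <- as.character(refs[[2]])

  ident <- align_contigs(fixture_assembly(c(c1 = r1)), refs)
  expect_identical(nrow(ident), 1L)
  expect_equal(ident$contig_start, 0)
  expect_equal(ident$contig_end, nchar(r1))
  expect_equal(ident$ref_start, 0)
  expect_identical(ident$mismatches, 0L)
  expect_identical(ident$strand, "+")

  flipped <- align_contigs(fixture_assembly(c(c1 = rc_chr(r1))), refs)
  expect_identical(nrow(flipped), 1L)
  expect_identical(flipped$strand, "-")
  expect_equal(flipped$contig_end - flipped$contig_start, nchar(r1))

  chimera <- paste0(substr(r1, 1, 3000), substr(r2, 1, 3000))
  blocks <- align_contigs(fixture_assembly(c(chi = chimera)), refs)
  expect_identical(nrow(blocks), 2L)
  expect_identical(sort(blocks$ref), c("g001", "g002"))
  mis <- count_misassemblies(blocks)
  expect_gte(mis$misassemblies, 1)
  expect_equal(mis$misassembled_contig_length, 6000)
})

test_that("genome fraction and duplication ratio follow interval arithmetic", {
  refs <- generate_genomes(1, c(10000, 10000), seed = 52)
  r <- as.character(refs[[1]])

  half <- align_contigs(fixture_assembly(c(c1 = substr(r, 1, 5000))), refs)
  expect_equal(genome_fraction(half, refs), 50)

  full <- align_contigs(perfect_assembly(refs), refs)
  expect_equal(genome_fraction(full, refs), 100)
  expect_equal(duplication_ratio(full, refs), 1.0)

  twice <- align_contigs(fixture_assembly(c(a = r, b = r)), refs)
  expect_equal(duplication_ratio(twice, refs), 2.0)
  expect_equal(genome_fraction(twice, refs), 100)

  # overlapping partial covers: (600 + 600) aligned over 1000 covered
  refs1k <- generate_genomes(1, c(1000, 1000), seed = 53)
  rr <- as.character(refs1k[[1]])
  ov <- align_contigs(
    fixture_assembly(c(a = substr(rr, 1, 600), b = substr(rr, 401, 1000))),
    refs1k, min_block = 65)
  expect_equal(duplication_ratio(ov, refs1k), 1.2)
  expect_equal(genome_fraction(ov, refs1k), 100)
})

test_that("coverage metrics agree with a brute-force per-base counter", {
  set.seed(54)
  refs <- generate_genomes(3, c(2000, 9000), seed = 54)
  seqs <- as.character(refs)
  pieces <- list()
  for (i in 1:8) {
    g <- sample(names(seqs), 1)
    len <- nchar(seqs[[g]])
    a <- sample.int(len - 400, 1)
    b <- min(len, a + sample(300:2000, 1))
    s <- substr(seqs[[g]], a, b)
    if (runif(1) < 0.5) s <- rc_chr(s)
    pieces[[sprintf("p%02d", i)]] <- s
  }
  blocks <- align_contigs(fixture_assembly(unlist(pieces)), refs)
  oracle <- brute_coverage_metrics(blocks, refs)
  expect_equal(genome_fraction(blocks, refs), oracle$genome_fraction)
  expect_equal(duplication_ratio(blocks, refs), oracle$duplication_ratio)
})

test_that("small positional inconsistencies count as local misassemblies", {
  refs <- generate_genomes(1, c(6000, 6000), seed = 55)
  r <- as.character(refs[[1]])
  # 500 bp of reference skipped with no contig gap: local (50..999)
  jumpy <- paste0(substr(r, 1, 3000), substr(r, 3501, 6000))
  blocks <- align_contigs(fixture_assembly(c(j = jumpy)), refs)
  mis <- count_misassemblies(blocks)
  expect_identical(mis$misassemblies, 0L)
  expect_identical(mis$local_misassemblies, 1L)

  # 2 kbp skipped: extensive
  wide <- paste0(substr(r, 1, 2000), substr(r, 4001, 6000))
  mis2 <- count_misassemblies(
    align_contigs(fixture_assembly(c(w = wide)), refs))
  expect_identical(mis2$misassemblies, 1L)

  perfect <- align_contigs(perfect_assembly(refs), refs)
  mis0 <- count_misassemblies(perfect)
  expect_identical(mis0$misassemblies, 0L)
  expect_identical(mis0$local_misassemblies, 0L)
  expect_equal(mis0$misassembled_contig_length, 0)
})

test_that("mismatch rates are per aligned 100 kbp", {
  refs <- generate_genomes(1, c(10000, 10000), seed = 56)
  r <- as.character(refs[[1]])
  mutated <- r
  pos <- 4321
  old <- substr(mutated, pos, pos)
  substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  blocks <- align_contigs(fixture_assembly(c(m = mutated)), refs)
  expect_equal(mismatches_per_100kbp(blocks), 10)

  clean <- align_contigs(perfect_assembly(refs), refs)
  expect_equal(mismatches_per_100kbp(clean), 0)
})

test_that("contiguity statistics match hand arithmetic", {
  one <- contiguity_stats(fixture_assembly(c(x = strrep("ACGT", 100))))
  expect_equal(one$auN, 400)
  expect_equal(one$N50, 400)

  two <- contiguity_stats(
    fixture_assembly(c(a = strrep("A", 100), b = strrep("C", 300))))
  expect_equal(two$auN, 250)
  expect_equal(two$N50, 300)
  expect_equal(two$total_len_ge_50kbp, 0)

  expect_warning(zero <- contiguity_stats(fixture_assembly(character(0))),
                 "empty")
  expect_equal(zero$N50, 0)
})

test_that("genome fraction never decreases when contigs are added", {
  refs <- generate_genomes(2, c(4000, 4000), seed = 57)
  seqs <- as.character(refs)
  parts <- c(a = substr(seqs[[1]], 1, 2000), b = substr(seqs[[2]], 1000, 3000),
             c = substr(seqs[[1]], 1500, 3500))
  gf <- vapply(1:3, function(m) {
    genome_fraction(align_contigs(fixture_assembly(parts[1:m]), refs), refs)
  }, 0)
  expect_true(all(diff(gf) >= 0))
})

test_that("read alignment against an assembly reflects its content", {
  refs <- generate_genomes(3, c(5000, 5000), seed = 58)
  prof <- assign_abundances(refs, 2,
                            abundance = matrix(c(0.9, 0.05, 0.05,
                                                 0.9, 0.05, 0.05), 2,
                                               byrow = TRUE))
  reads <- simulate_reads(prof, refs, depth = 5000, error_rate = 0,
                          weighted = FALSE, seed = 59)

  own <- read_alignment_eval(reads, perfect_assembly(refs))
  expect_true(all(own$overall_alignment_pct > 99.5))

  dom <- read_alignment_eval(reads, perfect_assembly(refs[1]))
  sd_binom <- 100 * sqrt(0.9 * 0.1 / 10000)
  expect_true(all(abs(dom$overall_alignment_pct - 90) < 3 * sd_binom + 0.5))

  none <- read_alignment_eval(reads,
                              fixture_assembly(c(z = strrep("ACGT", 100))))
  expect_true(all(none$overall_alignment_pct == 0))

  report <- evaluate_assembly(perfect_assembly(refs), refs, reads,
                              label = "perfect")
  expect_equal(report$genome_fraction, 100)
  expect_equal(report$duplication_ratio, 1.0)
  expect_identical(report$misassemblies, 0L)
})
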