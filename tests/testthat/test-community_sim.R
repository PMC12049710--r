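test_that("genome generation honours length, GC and determinism contracts", {
  one <- generate_genomes(1, c(1000, 1000), gc = 0.5, seed = 7)
  expect_equal(Biostrings::width(one), 1000)

  again <- generate_genomes(1, c(1000, 1000), gc = 0.5, seed = 7)
  expect_identical(as.character(one), as.character(again))

  many <- generate_genomes(50, c(5000, 20000), gc = 0.4, seed = 1)
  freq <- colSums(Biostrings::alphabetFrequency(many)[, c("A", "C", "G", "T")])
  gc_obs <- (freq[["C"]] + freq[["G"]]) / sum(freq)
  expect_lt(abs(gc_obs - 0.4), 0.02)

  expect_true(all(grepl("^[ACGT]+$", as.character(many))))
  expect_false(anyDuplicated(names(many)) > 0)
  expect_error(generate_genomes(3, c(1000, 2000), gc = 1.2), "gc")
  expect_error(generate_genomes(3, c(2000, 1000)), "length_range")
})

test_that("abundance profiles are normalised with the requested core structure", {
  refs <- generate_genomes(3, c(1000, 1000), seed = 1)
  prof <- assign_abundances(refs, 1, abundance = matrix(c(0.9, 0.05, 0.05), 1))
  curve <- cumulative_abundance_curve(prof)
  expect_equal(curve$taxa_fraction, c(1 / 3, 2 / 3, 1))
  expect_equal(curve$cumulative_pct, c(90, 95, 100))

  refs20 <- generate_genomes(20, c(1000, 2000), seed = 2)
  prof20 <- assign_abundances(refs20, n_samples = 10, model = "lognormal",
                              core_fraction = 0.25, seed = 3)
  mat <- abundance_matrix(prof20)
  expect_true(all(abs(rowSums(mat) - 1) < 1e-9))
  expect_identical(sum(colSums(presence_matrix(prof20)) == 10), 5L)
  # presence/abundance coupling
  expect_identical(unname(mat > 0), unname(presence_matrix(prof20)))

  # log-like: cumulative curve is concave (increments non-increasing)
  incr <- diff(c(0, cumulative_abundance_curve(prof20)$cumulative_pct))
  expect_true(all(diff(incr) < 1e-9))

  expect_error(
    assign_abundances(refs, 1, abundance = matrix(c(0, 0, 0), 1)),
    "non-normalizable")
})

test_that("uniform profiles give a straight cumulative curve ending at 100%", {
  refs <- generate_genomes(5, c(1000, 1000), seed = 4)
  prof <- assign_abundances(refs, 2, abundance = matrix(0.2, 2, 5))
  curve <- cumulative_abundance_curve(prof)
  expect_equal(curve$cumulative_pct, 100 * curve$taxa_fraction)

  prof2 <- assign_abundances(refs, 3, core_fraction = 0.4, seed = 5)
  expect_equal(dplyr::last(cumulative_abundance_curve(prof2)$cumulative_pct),
               100, tolerance = 1e-6)
})

test_that("simulated reads are faithful to their origin genomes", {
  refs <- generate_genomes(3, c(2000, 4000), seed = 6)
  prof <- assign_abundances(refs, 2, core_fraction = 1, seed = 6)
  reads <- simulate_reads(prof, refs, depth = 300, error_rate = 0, seed = 8)

  expect_identical(vapply(reads, nrow, 0L), c(s01 = 300L, s02 = 300L))
  seqs <- as.character(refs)
  r <- reads[[1]]
  rc_refs <- vapply(seqs, function(s) rc_chr(s), "")
  ok1 <- mapply(function(m, o) grepl(m, seqs[o], fixed = TRUE) ||
                  grepl(m, rc_refs[o], fixed = TRUE), r$mate1, r$origin)
  ok2 <- mapply(function(m, o) grepl(m, seqs[o], fixed = TRUE) ||
                  grepl(m, rc_refs[o], fixed = TRUE), r$mate2, r$origin)
  expect_true(all(ok1) && all(ok2))

  # provenance: the mate can be reproduced from the truth coordinates
  read_len <- attr(r, "read_len")
  fwd <- r$strand == "+"
  from_truth <- ifelse(fwd,
    substring(seqs[r$origin], r$start + 1, r$start + read_len),
    rc_chr(substring(seqs[r$origin], r$start + 1, r$start + read_len)))
  expect_identical(unname(from_truth[fwd]), r$mate1[fwd])
})

test_that("read origins follow the abundance model", {
  refs <- generate_genomes(3, c(5000, 5000), seed = 9)   # equal lengths
  prof <- assign_abundances(refs, 1,
                            abundance = matrix(c(0.9, 0.05, 0.05), 1))
  reads <- simulate_reads(prof, refs, depth = 200000, error_rate = 0,
                          weighted = FALSE, seed = 10)[[1]]
  n_a <- sum(reads$origin == "g001")
  sd_binom <- sqrt(200000 * 0.9 * 0.1)   # ~134
  expect_lt(abs(n_a - 180000), 3 * sd_binom)

  # zero abundance => zero reads
  prof0 <- assign_abundances(refs, 1, abundance = matrix(c(0.5, 0.5, 0), 1))
  reads0 <- simulate_reads(prof0, refs, depth = 2000, seed = 11)[[1]]
  expect_identical(sum(reads0$origin == "g003"), 0L)
})

test_that("length-weighted multinomial fidelity holds at depth", {
  refs <- generate_genomes(4, c(2000, 8000), seed = 12)
  prof <- assign_abundances(refs, 1, core_fraction = 1, seed = 12)
  reads <- simulate_reads(prof, refs, depth = 100000, seed = 13)[[1]]
  w <- abundance_matrix(length_weighted_abundance(prof, refs))[1, ]
  obs <- table(factor(reads$origin, levels = names(w))) / nrow(reads)
  for (g in names(w)) {
    sd_g <- sqrt(w[[g]] * (1 - w[[g]]) / nrow(reads))
    expect_lt(abs(obs[[g]] - w[[g]]), 3 * sd_g + 1e-12)
  }
})

test_that("simulation is deterministic and per-sample streams are stable", {
  refs <- generate_genomes(2, c(2000, 2000), seed = 14)
  mat3 <- matrix(c(0.7, 0.3, 0.5, 0.5, 0.2, 0.8), 3, 2, byrow = TRUE)
  prof3 <- assign_abundances(refs, 3, abundance = mat3)
  prof2 <- assign_abundances(refs, 2, abundance = mat3[1:2, , drop = FALSE])

  a <- simulate_reads(prof3, refs, depth = 100, seed = 15)
  b <- simulate_reads(prof3, refs, depth = 100, seed = 15)
  expect_identical(a, b)

  two <- simulate_reads(prof2, refs, depth = 100, seed = 15)
  expect_identical(as.data.frame(a[[1]]), as.data.frame(two[[1]]))
  expect_identical(as.data.frame(a[[2]]), as.data.frame(two[[2]]))
})

test_that("FASTQ round trip preserves pairs and is byte-stable", {
  refs <- generate_genomes(1, c(3000, 3000), seed = 16)
  prof <- assign_abundances(refs, 1, abundance = matrix(1, 1, 1))
  reads <- simulate_reads(prof, refs, depth = 50, seed = 17)[[1]]

  dir <- withr::local_tempdir()
  paths <- write_sample_fastq(reads, dir)
  back <- read_sample_fastq(paths[1], paths[2])
  expect_identical(back$mate1, reads$mate1)
  expect_identical(back$mate2, reads$mate2)
  expect_identical(back$pair_id, reads$pair_id)

  dir2 <- withr::local_tempdir()
  paths2 <- write_sample_fastq(reads, dir2)
  expect_identical(readLines(gzfile(paths[1])), readLines(gzfile(paths2[1])))

  write_profile_tsv(prof, file.path(dir, "profile.tsv"))
  write_truth_tsv(list(s01 = reads), file.path(dir, "truth.tsv.gz"))
  expect_true(file.exists(file.path(dir, "truth.tsv.gz")))
})

test_that("deterministic tiling covers every fragment start", {
  refs <- generate_genomes(1, c(1200, 1200), seed = 18)
  tiles <- tile_read_pairs(refs, read_len = 100, insert = 300, step = 1,
                           copies = 2)
  expect_identical(nrow(tiles), 2L * (1200L - 300L + 1L))
  g <- as.character(refs[[1]])
  expect_true(all(mapply(function(m, s) identical(m, substr(g, s + 1, s + 100)),
                         tiles$mate1, tiles$start)))
})
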