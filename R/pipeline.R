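#' Traditional one-step co-assembly
#'
#' Pools the pairs of every sample and runs the assembler once — the baseline
#' the sequential strategy is compared against.
#'
#' @param readsets Named list of `sample_reads`.
#' @param k,min_count,min_contig_len Assembler parameters
#'   (see [assemble_reads()]).
#' @return A `coassembly_run`: list with `assembly` and `report` (stage table,
#'   pair accounting).
#' @export
run_traditional <- function(readsets, k = 31, min_count = 2,
                            min_contig_len = 200) {
  check_readsets(readsets)
  total_pairs <- sum(vapply(readsets, nrow, 0L))
  t0 <- proc.time()[["elapsed"]]
  assembly <- assemble_reads(readsets, k, min_count, min_contig_len)
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- list(
    mode = "traditional",
    stages = tibble(stage = "co-assembly", input_pairs = total_pairs,
                    seconds = elapsed),
    mapping = NULL,
    total_pairs = total_pairs,
    step3_pairs = total_pairs,
    step3_fraction = 1,
    step3_pair_ids = unlist(lapply(readsets, `[[`, "pair_id"),
                            use.names = FALSE),
    subset = NULL
  )
  structure(list(assembly = assembly, report = report),
            class = "coassembly_run")
}

#' Sequential three-step co-assembly
#'
#' Step 1 co-assembles the subset samples. Step 2 maps every sample (including
#' the subset samples) to the step-1 assembly and keeps the pairs that fail to
#' align concordantly. Step 3 co-assembles the subset samples' full raw pairs
#' together with the unaligned pools of the non-subset samples (subset pools
#' are excluded so no pair enters step 3 twice).
#'
#' @inheritParams run_traditional
#' @param subset Character vector of sample ids seeding step 1 (non-empty,
#'   all present in `readsets`).
#' @param mapper Mapper parameters ([map_params()]).
#' @param keep_discordant Retain discordant pairs in the unaligned pools
#'   (default TRUE; see [partition_sample()]).
#' @return A `coassembly_run` whose report records per-stage input sizes, the
#'   per-sample mapping summary with pool sizes, and the step-3 input fraction.
#' @export
run_sequential <- function(readsets, subset, k = 31, min_count = 2,
                           min_contig_len = 200, mapper = map_params(),
                           keep_discordant = TRUE) {
  check_readsets(readsets)
  if (length(subset) == 0) abort("subset must be non-empty in sequential mode")
  if (!all(subset %in% names(readsets)))
    abort("subset contains sample ids missing from the read sets")
  total_pairs <- sum(vapply(readsets, nrow, 0L))
  subset_sets <- readsets[subset]
  subset_pairs <- sum(vapply(subset_sets, nrow, 0L))

  t0 <- proc.time()[["elapsed"]]
  step1 <- assemble_reads(subset_sets, k, min_count, min_contig_len)
  t1 <- proc.time()[["elapsed"]]
  if (nrow(step1) == 0)
    abort("step-1 assembly is empty: the subset is too shallow to seed the pipeline")

  index <- build_map_index(step1, mapper$k_index)
  partitions <- lapply(readsets, partition_sample, index = index,
                       params = mapper, keep_discordant = keep_discordant)
  t2 <- proc.time()[["elapsed"]]
  mapping <- bind_rows(lapply(partitions, `[[`, "summary")) %>%
    mutate(pool_pairs = vapply(partitions, function(p) nrow(p$pool), 0L),
           in_subset = .data$sample_id %in% subset)

  pools <- lapply(partitions[setdiff(names(readsets), subset)], `[[`, "pool")
  step3_input <- c(subset_sets, pools)
  step3_pairs <- sum(vapply(step3_input, nrow, 0L))
  step3 <- assemble_reads(step3_input, k, min_count, min_contig_len)
  t3 <- proc.time()[["elapsed"]]

  report <- list(
    mode = "sequential",
    stages = tibble(
      stage = c("step1_subset_assembly", "step2_mapping", "step3_final_assembly"),
      input_pairs = c(subset_pairs, total_pairs, step3_pairs),
      seconds = c(t1 - t0, t2 - t1, t3 - t2)
    ),
    mapping = mapping,
    total_pairs = total_pairs,
    subset_pairs = subset_pairs,
    step3_pairs = step3_pairs,
    step3_fraction = step3_pairs / total_pairs,
    step3_pair_ids = unlist(lapply(step3_input, `[[`, "pair_id"),
                            use.names = FALSE),
    subset = subset,
    step1_assembly = step1
  )
  structure(list(assembly = step3, report = report),
            class = "coassembly_run")
}

#' @export
print.coassembly_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("%s co-assembly: %d contigs (%s bp) from %s of %s input pairs (%.1f%%)\n",
              r$mode, nrow(x$assembly),
              format(sum(x$assembly$length), big.mark = ","),
              format(r$step3_pairs, big.mark = ","),
              format(r$total_pairs, big.mark = ","),
              100 * r$step3_fraction))
  print(r$stages)
  invisible(x)
}

#' Compare co-assembly strategies on one dataset
#'
#' Evaluates each run (or bare assembly) with [evaluate_assembly()] against the
#' same references and read sets, and appends the step-3 input share of each
#' strategy. All runs must cover the same samples.
#'
#' @param runs Named list of `coassembly_run` objects (or `assembly` tibbles).
#' @param refs Reference genomes for the reference-based metrics.
#' @param readsets Named list of `sample_reads` for the reference-free metric.
#' @param params Mapper parameters.
#' @return A `strategy_comparison` tibble, one row per strategy.
#' @export
compare_strategies <- function(runs, refs, readsets, params = map_params()) {
  if (length(runs) < 2) abort("need at least two strategies to compare")
  rows <- lapply(names(runs), function(nm) {
    run <- runs[[nm]]
    asm <- if (inherits(run, "coassembly_run")) run$assembly else run
    row <- evaluate_assembly(asm, refs, readsets, params, label = nm)
    row$step3_input_pct <- if (inherits(run, "coassembly_run"))
      100 * run$report$step3_fraction else NA_real_
    row
  })
  structure(bind_rows(rows),
            class = c("strategy_comparison", class(tibble())))
}

#' @export
tidy.strategy_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.strategy_comparison <- function(x, ...) {
  fit <- tryCatch(fit_alignment_model(x), error = function(e) NULL)
  tibble(
    n_strategies = nrow(x),
    genome_fraction_range = diff(range(x$genome_fraction)),
    alignment_range = diff(range(x$mean_read_alignment_pct)),
    alignment_log_gf_r_squared =
      if (is.null(fit)) NA_real_
      else suppressWarnings(summary(fit)$r.squared)
  )
}

#' @export
autoplot.strategy_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$genome_fraction,
                               y = .data$mean_read_alignment_pct,
                               label = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean recovered genome fraction (%) [log scale]",
                  y = "Mean overall read alignment (%)") +
    ggplot2::theme_minimal()
}

#' Rank candidate subsets by initial-assembly read alignment
#'
#' Assembles each candidate subset and scores it by the mean overall read
#' alignment of all samples against that initial assembly — a cheap way to
#' pick the subset most representative of the whole community before
#' committing to the full sequential run.
#'
#' @inheritParams run_sequential
#' @param candidates List of character vectors of sample ids.
#' @return A tibble `subset`, `n_samples`, `mean_alignment_pct`, sorted best
#'   first.
#' @export
rank_subsets <- function(readsets, candidates, k = 31, min_count = 2,
                         min_contig_len = 200, mapper = map_params()) {
  check_readsets(readsets)
  rows <- lapply(candidates, function(ss) {
    asm <- assemble_reads(readsets[ss], k, min_count, min_contig_len)
    ra <- read_alignment_eval(readsets, asm, mapper)
    tibble(subset = paste(ss, collapse = "+"), n_samples = length(ss),
           mean_alignment_pct = attr(ra, "mean"))
  })
  bind_rows(rows) %>% arrange(desc(.data$mean_alignment_pct))
}

check_readsets <- function(readsets) {
  if (length(readsets) == 0) abort("no samples supplied")
  if (is.null(names(readsets)) || any(names(readsets) == ""))
    abort("readsets must be a named list of sample_reads")
  invisible(TRUE)
}
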