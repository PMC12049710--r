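#' Assign per-sample relative abundances to a reference set
#'
#' Builds a multi-sample community profile with the structure typical of gut
#' metagenome surveys: a steeply decreasing (log-like) ranked abundance
#' distribution, a core of taxa present in every sample, and the remaining taxa
#' present in only a random subset of samples. The most abundant taxa form the
#' core, reproducing the mock-community picture of one dominant, ubiquitous
#' organism plus rare, patchy ones.
#'
#' Each taxon receives a base abundance from the chosen rank-abundance model;
#' per-sample abundances jitter the base multiplicatively, zero out absent
#' taxa, and renormalise so every sample's abundances sum to one.
#'
#' @param refs Reference genomes ([Biostrings::DNAStringSet] or named character
#'   vector); taxa are its names.
#' @param n_samples Number of samples (>= 1).
#' @param model `"lognormal"` (base abundances i.i.d. lognormal, then ranked) or
#'   `"log_series"` (Fisher log-series-like, abundance proportional to
#'   `theta^rank / rank`).
#' @param core_fraction Fraction of taxa present in all samples (the
#'   `round(core_fraction * n_taxa)` most abundant taxa).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param sdlog Lognormal sd (log scale) of base abundances; larger = steeper.
#' @param sample_sdlog Per-sample multiplicative jitter sd (log scale).
#' @param presence_prob Bernoulli probability that a non-core taxon is present
#'   in a given sample. Each non-core taxon is forced to have at least one
#'   presence and (for >= 2 samples) at least one absence.
#' @param theta Log-series decay parameter (only for `model = "log_series"`).
#' @param abundance Optional explicit sample-by-taxon abundance matrix; rows
#'   are normalised to sum to one and zero entries become absences. Overrides
#'   `model`.
#' @return A `community_profile`: a tibble with columns `sample_id`, `taxon`,
#'   `abundance`, `present`, carrying the taxon and sample order as attributes.
#' @examples
#' refs <- generate_genomes(5, c(1000, 2000), seed = 1)
#' prof <- assign_abundances(refs, n_samples = 4, core_fraction = 0.4, seed = 2)
#' abundance_matrix(prof)
#' @export
assign_abundances <- function(refs, n_samples,
                              model = c("lognormal", "log_series"),
                              core_fraction = 0.25, seed = 1,
                              sdlog = 1.5, sample_sdlog = 0.5,
                              presence_prob = 0.3, theta = 0.96,
                              abundance = NULL) {
  taxa <- names(as_seq_chr(refs))
  if (is.null(taxa)) abort("reference sequences must be named")
  n_taxa <- length(taxa)

  if (!is.null(abundance)) {
    abundance <- as.matrix(abundance)
    if (ncol(abundance) != n_taxa)
      abort("explicit abundance matrix must have one column per taxon")
    if (any(abundance < 0) || any(rowSums(abundance) <= 0))
      abort("explicit abundance matrix has a non-normalizable row")
    mat <- abundance / rowSums(abundance)
    samples <- rownames(mat) %||% sprintf("s%02d", seq_len(nrow(mat)))
    rownames(mat) <- samples
    colnames(mat) <- taxa
    return(new_community_profile(mat))
  }

  model <- match.arg(model)
  stopifnot(n_samples >= 1)
  if (core_fraction < 0 || core_fraction > 1)
    abort("core_fraction must be in [0, 1]")
  set.seed(seed %% .Machine$integer.max)

  base <- switch(model,
    lognormal = sort(rlnorm(n_taxa, meanlog = 0, sdlog = sdlog),
                     decreasing = TRUE),
    log_series = theta^seq_len(n_taxa) / seq_len(n_taxa)
  )
  base <- base / sum(base)

  # rank taxa by base abundance: taxa keep their ids, ranks get the abundances
  n_core <- round(core_fraction * n_taxa)
  present <- matrix(TRUE, n_samples, n_taxa)
  if (n_core < n_taxa) {
    for (j in seq(n_core + 1L, n_taxa)) {
      p <- runif(n_samples) < presence_prob
      if (!any(p)) p[sample.int(n_samples, 1L)] <- TRUE
      if (n_samples >= 2L && all(p)) p[sample.int(n_samples, 1L)] <- FALSE
      present[, j] <- p
    }
  }
  jitter <- matrix(exp(stats::rnorm(n_samples * n_taxa, 0, sample_sdlog)),
                   n_samples, n_taxa)
  mat <- sweep(jitter, 2L, base, `*`) * present
  empty <- rowSums(mat) == 0
  if (any(empty)) {  # pathological: nothing present in a sample
    present[empty, 1L] <- TRUE
    mat[empty, 1L] <- base[1L]
  }
  mat <- mat / rowSums(mat)
  rownames(mat) <- sprintf("s%02d", seq_len(n_samples))
  colnames(mat) <- taxa
  new_community_profile(mat)
}

new_community_profile <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  tb <- tibble(
    sample_id = rep(rownames(mat), times = ncol(mat)),
    taxon = rep(colnames(mat), each = nrow(mat)),
    abundance = as.vector(mat),
    present = as.vector(mat) > 0
  ) %>%
    arrange(match(.data$sample_id, rownames(mat)),
            match(.data$taxon, colnames(mat)))
  structure(tb,
            taxa = colnames(mat), samples = rownames(mat),
            class = c("community_profile", class(tb)))
}

#' Matrix views of a community profile
#'
#' @param profile A `community_profile`.
#' @return `abundance_matrix()`: the sample-by-taxon relative-abundance matrix
#'   (rows sum to 1); `presence_matrix()`: the logical presence matrix.
#' @export
abundance_matrix <- function(profile) {
  taxa <- attr(profile, "taxa")
  samples <- attr(profile, "samples")
  mat <- matrix(0, length(samples), length(taxa),
                dimnames = list(samples, taxa))
  mat[cbind(match(profile$sample_id, samples), match(profile$taxon, taxa))] <-
    profile$abundance
  mat
}

#' @rdname abundance_matrix
#' @export
presence_matrix <- function(profile) {
  abundance_matrix(profile) > 0
}

#' Reweight a profile by genome length
#'
#' Shotgun read share scales with genome size: a sample's expected fraction of
#' reads from taxon j is proportional to `abundance[j] * length[j]`. This
#' converts an organismal abundance profile into the corresponding
#' length-weighted read-share profile.
#'
#' @param profile A `community_profile`.
#' @param refs The reference genomes the profile was built over.
#' @return A `community_profile` of per-sample read shares (rows sum to 1).
#' @export
length_weighted_abundance <- function(profile, refs) {
  seqs <- as_seq_chr(refs)
  mat <- abundance_matrix(profile)
  lens <- nchar(seqs)[colnames(mat)]
  if (anyNA(lens)) abort("profile taxa missing from the reference set")
  w <- sweep(mat, 2L, lens, `*`)
  w <- w / rowSums(w)
  new_community_profile(w)
}

#' Cumulative relative abundance curve
#'
#' Orders taxa by mean relative abundance across samples (descending) and
#' accumulates: the curve answers "what share of the community do the top
#' k taxa hold?". For log-like communities it is strongly concave — most reads
#' come from a small fraction of the genomes.
#'
#' @param profile A `community_profile`.
#' @return A tibble with one row per taxon rank: `taxon`, `rank`,
#'   `taxa_fraction` (rank / n taxa) and `cumulative_pct` (ends at 100).
#' @examples
#' refs <- generate_genomes(3, c(1000, 1000), seed = 1)
#' prof <- assign_abundances(refs, 1, abundance = matrix(c(0.9, 0.05, 0.05), 1))
#' cumulative_abundance_curve(prof)
#' @export
cumulative_abundance_curve <- function(profile) {
  mat <- abundance_matrix(profile)
  mean_ab <- colMeans(mat)
  ord <- order(mean_ab, decreasing = TRUE)
  n <- length(ord)
  tibble(
    taxon = colnames(mat)[ord],
    rank = seq_len(n),
    taxa_fraction = seq_len(n) / n,
    cumulative_pct = unname(100 * cumsum(mean_ab[ord]))
  )
}

#' Plot the cumulative relative abundance curve
#'
#' @param profile A `community_profile`.
#' @return A ggplot object.
#' @export
plot_cumulative_abundance <- function(profile) {
  curve <- cumulative_abundance_curve(profile)
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$taxa_fraction,
                               y = .data$cumulative_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Fraction of genomes (ranked by mean abundance)",
                  y = "Cumulative relative abundance (%)") +
    ggplot2::theme_minimal()
}

#' Write a profile as TSV
#'
#' Sample-by-taxon abundance matrix, one row per sample.
#' @param profile A `community_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  mat <- abundance_matrix(profile)
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
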