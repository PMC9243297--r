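# Sequencing-depth determination: sub-sample a deeply sequenced sample,
# re-quantify k-mers, and measure rank concordance (Spearman R squared)
# against the full-depth table across a range of k.

#' Sub-sample reads without replacement
#'
#' Uniform sample of `depth` reads, deterministic under `seed`; the
#' output preserves the input order (as if the pool had simply been
#' sequenced less deeply).
#'
#' @param reads Read tibble.
#' @param depth Number of reads to keep (`<= nrow(reads)`).
#' @param seed Integer seed.
#' @return A read tibble with `depth` rows.
#' @export
subsample_reads <- function(reads, depth, seed) {
  reads <- check_reads(reads)
  depth <- as.integer(depth)
  if (depth < 1L) abort("depth must be >= 1")
  if (depth > nrow(reads)) {
    abort(sprintf("requested depth %d exceeds available reads (%d)",
                  depth, nrow(reads)),
          class = "selexkit_depth_error")
  }
  idx <- with_seed(seed, sort(sample.int(nrow(reads), depth)))
  reads[idx, , drop = FALSE]
}

#' Squared Spearman rank correlation
#'
#' Spearman's rank correlation (average ranks for ties) squared, as used
#' for depth concordance. Squaring discards the sign: a perfectly
#' reverse-ranked vector also scores 1; set `squared = FALSE` to inspect
#' the raw coefficient.
#'
#' @param x,y Equal-length numeric vectors (length >= 2, not constant).
#' @param squared Return the square (default) or the raw coefficient.
#' @return A number in `[0, 1]` (or `[-1, 1]` when `squared = FALSE`).
#' @export
spearman_r2 <- function(x, y, squared = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least 2 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a constant vector",
          class = "selexkit_constant_error")
  }
  rho <- cor(x, y, method = "spearman")
  if (squared) rho^2 else rho
}

#' Depth sufficiency by sub-sampling rank concordance
#'
#' Emulates sequencing the same pool at lower depth: for each requested
#' depth the reads are sub-sampled once (without replacement), k-mer
#' presence fractions are recomputed for every `k`, and their ranks are
#' compared with the full-depth fractions via [spearman_r2()]. A depth
#' equal to the full pool gives exactly 1 for every k. Longer k-mers
#' lose concordance faster as depth drops, because the 4^k table
#' outgrows the read count.
#'
#' @param reads Read tibble (the full-depth sample).
#' @param depths Integer vector of sub-sampling depths (each
#'   `<= nrow(reads)`).
#' @param k_values Word lengths to evaluate (default 5:10).
#' @param seed Master seed; one sub-sample seed is derived per depth and
#'   shared across `k_values`.
#' @return A tibble of class `coverage_report` with columns `depth`,
#'   `k`, `r2`, and attributes `seed`, `n_reads`.
#' @export
coverage_analysis <- function(reads, depths, k_values = 5:10, seed) {
  reads <- check_reads(reads)
  depths <- as.integer(depths)
  k_values <- vapply(k_values, check_k, integer(1))
  if (any(depths > nrow(reads))) {
    abort("all depths must be <= the number of reads",
          class = "selexkit_depth_error")
  }
  full_fr <- lapply(k_values, function(k) presence_fraction_vector(reads, k))
  names(full_fr) <- as.character(k_values)
  dseeds <- derive_seeds(seed, length(depths))
  rows <- list()
  for (di in seq_along(depths)) {
    sub <- subsample_reads(reads, depths[di], dseeds[di])
    for (k in k_values) {
      fr <- presence_fraction_vector(sub, k)
      full <- full_fr[[as.character(k)]]
      # identical vectors (e.g. depth == full depth) are concordant by
      # definition; bypass floating-point noise in the rank correlation
      r2 <- if (identical(fr, full)) 1.0 else spearman_r2(fr, full)
      rows[[length(rows) + 1L]] <-
        tibble(depth = depths[di], k = k, r2 = r2)
    }
  }
  out <- bind_rows(rows)
  structure(out, seed = as.integer(seed), n_reads = nrow(reads),
            class = c("coverage_report", class(out)))
}

# Presence-fraction vector over all 4^k k-mers without materialising the
# kmer string column (coverage runs up to k = 10, i.e. 4^10 entries).
presence_fraction_vector <- function(reads, k) {
  nk <- as.integer(4^k)
  sw <- scan_windows(reads$seq, k)
  key <- unique((sw$id - 1) * as.double(nk) + sw$code)
  tabulate(as.integer(key %% nk) + 1L, nbins = nk) / nrow(reads)
}

#' Overlap of the top-m k-mers of two abundance tables
#'
#' `|top_m(x) intersect top_m(y)| / m` using the deterministic tie rule
#' of [top_kmers()].
#'
#' @param x,y `kmer_table`s or tibbles with `kmer` and `fraction`.
#' @param m Number of top k-mers to compare.
#' @return A fraction in `[0, 1]`.
#' @export
top_overlap <- function(x, y, m) {
  tx <- top_kmers(x, m)$kmer
  ty <- top_kmers(y, m)$kmer
  length(intersect(tx, ty)) / m
}
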