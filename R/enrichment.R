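# Cycle-0-normalised enrichment. Every selected sample is compared with
# the unselected random library (cycle 0) of its own replicate; the
# no-protein negative controls travel through the same computation and
# are reported side by side, never subtracted.

#' Number of A/T letters in a k-mer
#'
#' The A/T-content category of a k-mer: 0 (all G/C) to k (all A/T). At
#' k = 5 this partitions the 1024 k-mers into six categories with
#' `choose(5, j) * 32` members each.
#'
#' @param kmer Character vector of k-mers over `{A,C,G,T}`.
#' @return Integer vector of A/T counts.
#' @export
#' @examples
#' at_category(c("ATATA", "GCGCG", "ACGTA")) # 5 0 3
at_category <- function(kmer) {
  nchar(kmer) - nchar(gsub("[AT]", "", kmer))
}

#' Enrichment configuration
#'
#' @param pseudocount Non-negative value added to presence counts (and to
#'   the read totals) so that k-mers absent from a sample still yield a
#'   finite, symmetric fold change; must be positive whenever any
#'   reference presence is zero. Default 1 (Laplace-style).
#' @param pairing `"matched_library"` (default): each sample is
#'   normalised against the cycle-0 sample of the same replicate library,
#'   since independently synthesised libraries start from slightly
#'   different sequence distributions. `"pooled_cycle0"`: all cycle-0
#'   samples are pooled into a single reference.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(pseudocount = 1,
                              pairing = c("matched_library", "pooled_cycle0")) {
  pairing <- match.arg(pairing)
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    abort("pseudocount must be a non-negative number")
  }
  structure(list(pseudocount = pseudocount, pairing = pairing),
            class = "enrichment_config")
}

#' Fold change of k-mer presence versus a reference sample
#'
#' For each k-mer `w`,
#' `FC(w) = ((p_s(w) + a) / (n_s + a)) / ((p_r(w) + a) / (n_r + a))`
#' where `p` are presence counts, `n` read totals and `a` the
#' pseudocount. Always finite and positive when `a > 0`; a sample
#' compared with itself gives exactly 1 everywhere.
#'
#' @param sample,reference `kmer_table`s from [count_kmers()] with the
#'   same `k` and canonical flag. The reference is normally a cycle-0
#'   sample.
#' @param pseudocount See [enrichment_config()].
#' @return A tibble with columns `kmer`, `fold_change`.
#' @export
fold_change <- function(sample, reference, pseudocount = 1) {
  ks <- kmer_attr(sample, "k"); kr <- kmer_attr(reference, "k")
  if (ks != kr) {
    abort(sprintf("k mismatch between sample (k=%d) and reference (k=%d)", ks, kr),
          class = "selexkit_mismatch_error")
  }
  if (kmer_attr(sample, "canonical") != kmer_attr(reference, "canonical")) {
    abort("sample and reference differ in canonical collapsing",
          class = "selexkit_mismatch_error")
  }
  a <- pseudocount
  if (a == 0 && any(reference$presence == 0)) {
    abort(paste0("reference has k-mers with zero presence and pseudocount is 0; ",
                 "use a positive pseudocount to obtain finite fold changes"),
          class = "selexkit_division_error")
  }
  ns <- kmer_attr(sample, "n_reads"); nr <- kmer_attr(reference, "n_reads")
  fc <- ((sample$presence + a) / (ns + a)) / ((reference$presence + a) / (nr + a))
  tibble(kmer = sample$kmer, fold_change = fc)
}

pool_cycle0 <- function(tables) {
  ref <- tables[[1]]
  pres <- Reduce(`+`, lapply(tables, function(t) t$presence))
  occ <- Reduce(`+`, lapply(tables, function(t) t$occurrence))
  out <- tibble(kmer = ref$kmer, occurrence = occ, presence = pres)
  new_kmer_table(out, k = kmer_attr(ref, "k"),
                 n_reads = sum(vapply(tables, kmer_attr, integer(1), "n_reads")),
                 n_windows = sum(vapply(tables, kmer_attr, integer(1), "n_windows")),
                 canonical = kmer_attr(ref, "canonical"))
}

#' Cycle-0-normalised enrichment for a whole dataset
#'
#' Computes per-k-mer fold changes for every sample with cycle > 0 —
#' protein selections and no-protein controls alike — against its cycle-0
#' reference. Controls are carried as their own rows so they can be
#' plotted next to the protein series; they are never used to rescale
#' anything.
#'
#' @param tables Named list of `kmer_table`s, one per sample, with names
#'   matching `meta$sample_name`.
#' @param meta Sample metadata as returned by [read_sample_sheet()] (or
#'   any tibble with `sample_name`, `library`, `protein`, `cycle`).
#' @param config An [enrichment_config()].
#' @return A tibble of class `selex_enrichment` with columns `kmer`,
#'   `sample_name`, `protein`, `cycle`, `library`, `is_control`,
#'   `fraction`, `fold_change`, `at_category`, `reference_sample`.
#' @export
enrich_dataset <- function(tables, meta, config = enrichment_config()) {
  stopifnot(inherits(config, "enrichment_config"))
  need <- c("sample_name", "library", "protein", "cycle")
  if (!all(need %in% names(meta))) {
    abort(paste0("`meta` must have columns: ", paste(need, collapse = ", ")))
  }
  if (!"is_control" %in% names(meta)) {
    meta$is_control <- tolower(meta$protein) == "none"
  }
  targets <- meta[meta$cycle > 0, , drop = FALSE]
  missing_tab <- setdiff(c(targets$sample_name,
                           meta$sample_name[meta$cycle == 0]),
                         names(tables))
  if (length(missing_tab)) {
    abort(sprintf("no kmer_table supplied for sample(s): %s",
                  paste(missing_tab, collapse = ", ")))
  }
  refs0 <- meta[meta$cycle == 0, , drop = FALSE]
  pooled <- NULL
  if (config$pairing == "pooled_cycle0") {
    if (nrow(refs0) == 0) {
      abort("pooled_cycle0 pairing requires at least one cycle-0 sample")
    }
    pooled <- pool_cycle0(tables[refs0$sample_name])
  }
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    smeta <- targets[i, ]
    st <- tables[[smeta$sample_name]]
    if (config$pairing == "matched_library") {
      hit <- refs0[refs0$library == smeta$library, , drop = FALSE]
      if (nrow(hit) == 0) {
        abort(sprintf("sample '%s' (library %s, cycle %d) has no cycle-0 reference in its library",
                      smeta$sample_name, smeta$library, smeta$cycle),
              class = "selexkit_reference_error")
      }
      if (nrow(hit) > 1) {
        abort(sprintf("library %s has %d cycle-0 samples; the matched_library pairing needs exactly one",
                      smeta$library, nrow(hit)),
              class = "selexkit_reference_error")
      }
      ref <- tables[[hit$sample_name]]
      ref_name <- hit$sample_name
    } else {
      ref <- pooled
      ref_name <- "pooled_cycle0"
    }
    fc <- fold_change(st, ref, pseudocount = config$pseudocount)
    tibble(kmer = st$kmer,
           sample_name = smeta$sample_name,
           protein = smeta$protein,
           cycle = smeta$cycle,
           library = smeta$library,
           is_control = smeta$is_control,
           fraction = st$presence / kmer_attr(st, "n_reads"),
           fold_change = fc$fold_change,
           at_category = at_category(st$kmer),
           reference_sample = ref_name)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(kmer = character(), sample_name = character(),
                  protein = character(), cycle = integer(),
                  library = character(), is_control = logical(),
                  fraction = double(), fold_change = double(),
                  at_category = integer(), reference_sample = character())
  }
  k <- if (length(tables)) kmer_attr(tables[[1]], "k") else NA_integer_
  structure(out, k = k, pseudocount = config$pseudocount,
            class = c("selex_enrichment", class(out)))
}

#' Summarise enrichment by A/T-content category
#'
#' For each (protein, cycle, category): the mean fold change over k-mers
#' is computed within each replicate library, then averaged across
#' libraries; the dispersion is the standard deviation of those
#' per-library means — the technical variability between independent
#' SELEX libraries.
#'
#' @param e A `selex_enrichment` from [enrich_dataset()].
#' @return A tibble with columns `protein`, `cycle`, `is_control`,
#'   `at_category`, `mean_fc`, `sd_fc`, `n_kmers`, `n_libraries`.
#'   Groups backed by a single library get `sd_fc = 0` and a warning.
#' @export
summarize_by_category <- function(e) {
  per_lib <- e |>
    group_by(.data$protein, .data$cycle, .data$is_control, .data$library,
             .data$at_category) |>
    summarise(mfc = mean(.data$fold_change), n_kmers = n(), .groups = "drop")
  out <- per_lib |>
    group_by(.data$protein, .data$cycle, .data$is_control, .data$at_category) |>
    summarise(mean_fc = mean(.data$mfc),
              sd_fc = if (n() > 1) sd(.data$mfc) else 0,
              n_kmers = first(.data$n_kmers),
              n_libraries = n(),
              .groups = "drop")
  if (any(out$n_libraries == 1) && nrow(out) > 0) {
    warn("some (protein, cycle) groups have a single replicate library; their dispersion is reported as 0")
  }
  out
}

#' Write an enrichment table and its category summary to TSV
#'
#' @param e A `selex_enrichment`.
#' @param path Output TSV for the long table.
#' @param summary_path Optional output TSV for
#'   [summarize_by_category()].
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(e, path, summary_path = NULL) {
  readr::write_tsv(as_tibble(e), path)
  if (!is.null(summary_path)) {
    readr::write_tsv(suppressWarnings(summarize_by_category(e)), summary_path)
  }
  invisible(path)
}
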