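# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname count_kmers
#' @param x A `kmer_table`.
#' @param ... Unused.
#' @method tidy kmer_table
#' @export
tidy.kmer_table <- function(x, ...) {
  as_tibble(kmer_fractions(x))
}

#' @rdname count_kmers
#' @method glance kmer_table
#' @export
glance.kmer_table <- function(x, ...) {
  tibble(k = kmer_attr(x, "k"),
         n_reads = kmer_attr(x, "n_reads"),
         n_windows = kmer_attr(x, "n_windows"),
         canonical = kmer_attr(x, "canonical"),
         n_kmers_observed = sum(x$presence > 0))
}

#' @rdname enrich_dataset
#' @param x A `selex_enrichment`.
#' @param ... Unused.
#' @method tidy selex_enrichment
#' @export
tidy.selex_enrichment <- function(x, ...) as_tibble(x)

#' @rdname enrich_dataset
#' @method glance selex_enrichment
#' @export
glance.selex_enrichment <- function(x, ...) {
  tibble(k = attr(x, "k"),
         pseudocount = attr(x, "pseudocount"),
         n_samples = length(unique(x$sample_name)),
         n_proteins = length(unique(x$protein[!x$is_control])),
         cycles = paste(sort(unique(x$cycle)), collapse = "/"))
}

#' @rdname coverage_analysis
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) as_tibble(x)

#' @rdname coverage_analysis
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(n_reads = attr(x, "n_reads"),
         seed = attr(x, "seed"),
         n_depths = length(unique(x$depth)),
         min_r2 = min(x$r2))
}

#' @rdname validate_barcode_set
#' @param x A `barcode_report`.
#' @param ... Unused.
#' @method glance barcode_report
#' @export
glance.barcode_report <- function(x, ...) {
  tibble(n = x$n, length = x$length,
         min_pairwise_hamming = x$min_pairwise_hamming)
}
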