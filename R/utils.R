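# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the alphabet `{A,C,G,T,N}` (N maps to
#' N). Satisfies `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement(c("ACGTN", "TTTT"))
reverse_complement <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate DNA over {A,C,G,T} (+ N when allow_n); returns invisibly.
check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    abort(
      sprintf("%s contains characters outside the %s alphabet (first offender: %s)",
              what, if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}",
              x[which(bad)[1]]),
      class = "selexkit_alphabet_error"
    )
  }
  invisible(x)
}

# A read table is a tibble with at least columns id, seq, qual (qual may be
# NA for FASTA-derived reads; stored as a Phred+33 encoded string).
check_reads <- function(reads, need_qual = FALSE) {
  if (!is.data.frame(reads)) abort("`reads` must be a data frame / tibble")
  miss <- setdiff(c("id", "seq"), names(reads))
  if (length(miss)) {
    abort(paste0("`reads` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"qual" %in% names(reads)) reads$qual <- NA_character_
  if (need_qual && anyNA(reads$qual)) {
    abort("all reads must carry base qualities for this operation",
          class = "selexkit_quality_error")
  }
  has_q <- !is.na(reads$qual)
  if (any(nchar(reads$qual[has_q]) != nchar(reads$seq[has_q]))) {
    abort("quality strings must have the same length as their sequences",
          class = "selexkit_quality_error")
  }
  as_tibble(reads)
}

new_read_tibble <- function(id, seq, qual = NA_character_) {
  tibble(id = as.character(id), seq = as.character(seq),
         qual = as.character(qual))
}

#' Convert Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of Phred+33 encoded quality strings.
#' @return A list of integer vectors (one per element; `NULL` for `NA`).
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    utf8ToInt(q) - 33L
  })
}

# Evaluate code under a temporary RNG state (master seed), restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive n independent stream seeds from one master seed.
# Kept below 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

`%not-empty%` <- function(x, y) if (length(x)) x else y
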