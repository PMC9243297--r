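# Exhaustive k-mer quantification: every sample is summarised by the
# occurrence and read-presence counts of all 4^k k-mers, using a base-4
# integer encoding (A=0, C=1, G=2, T=3, leftmost base most significant).
# k is capped at 10: the table for k = 11 would hold 4^11 = 4,194,304
# entries per sample and is outside the intended scale of this toolkit.

KMER_MAX_K <- 10L

check_k <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("k must be a positive integer")
  if (k > KMER_MAX_K) {
    abort(sprintf("k = %d exceeds the supported limit of %d (the exhaustive 4^k table becomes impractical)",
                  k, KMER_MAX_K),
          class = "selexkit_capability_error")
  }
  k
}

#' Encode / decode k-mers as base-4 integers
#'
#' `encode_kmer()` maps a k-mer over `{A,C,G,T}` to an integer in
#' `[0, 4^k)` with A=0, C=1, G=2, T=3 and the leftmost base most
#' significant; `decode_kmer()` is its inverse. K-mers containing `N`
#' (or any other symbol) are not encodable and yield `NA` — callers skip
#' such windows.
#'
#' @param kmer Character vector of equal-length k-mers.
#' @param code Integer vector of codes.
#' @param k Word length (1–10).
#' @return An integer vector (`encode_kmer`) or character vector
#'   (`decode_kmer`).
#' @export
#' @examples
#' encode_kmer("AAAAA") # 0
#' encode_kmer("TTTTT") # 1023
#' decode_kmer(0:3, 1)  # A C G T
encode_kmer <- function(kmer) {
  if (!length(kmer)) return(integer())
  k <- unique(nchar(kmer))
  if (length(k) != 1) abort("all k-mers must have the same length")
  check_k(k)
  strtoi(chartr("ACGT", "0123", kmer), base = 4L)
}

#' @rdname encode_kmer
#' @export
decode_kmer <- function(code, k) {
  k <- check_k(k)
  cols <- vector("list", k)
  c <- as.integer(code)
  for (j in k:1) {
    cols[[j]] <- DNA_BASES[c %% 4L + 1L]
    c <- c %/% 4L
  }
  do.call(paste0, cols)
}

# encode(reverse_complement(decode(code))) without strings.
rc_code <- function(code, k) {
  out <- integer(length(code))
  c <- as.integer(code)
  for (j in seq_len(k)) {
    out <- out * 4L + (3L - c %% 4L)
    c <- c %/% 4L
  }
  out
}

# Scan all k-windows of `seqs`: returns codes and originating read index,
# with windows containing N (unencodable) skipped.
scan_windows <- function(seqs, k) {
  lens <- nchar(seqs)
  code_l <- list()
  id_l <- list()
  maxw <- if (length(lens)) max(lens) - k + 1L else 0L
  if (maxw >= 1L) {
    for (i in seq_len(maxw)) {
      sel <- which(lens >= i + k - 1L)
      cd <- strtoi(chartr("ACGT", "0123", substr(seqs[sel], i, i + k - 1L)),
                   base = 4L)
      ok <- !is.na(cd)
      code_l[[i]] <- cd[ok]
      id_l[[i]] <- sel[ok]
    }
  }
  list(code = unlist(code_l) %not-empty% integer(),
       id = unlist(id_l) %not-empty% integer())
}

#' Count all k-mers in a sample
#'
#' Exhaustively tallies every one of the `4^k` k-mers over all reads:
#' `occurrence` is the total number of k-windows equal to the k-mer and
#' `presence` the number of reads containing it at least once. Windows
#' containing `N` are skipped and excluded from the window total. With
#' `canonical = TRUE` each window is collapsed onto
#' `min(code, code of reverse complement)` before tallying, so all mass
#' sits on canonical k-mers (total occurrence is preserved).
#'
#' @param reads Read tibble.
#' @param k Word length, 1–10.
#' @param canonical Collapse reverse-complement pairs (default `FALSE`:
#'   the read strand is counted as sequenced).
#' @return A tibble of class `kmer_table` with `4^k` rows (columns
#'   `kmer`, `occurrence`, `presence`, in encoding order) and attributes
#'   `k`, `n_reads`, `n_windows`, `canonical`.
#' @export
count_kmers <- function(reads, k, canonical = FALSE) {
  k <- check_k(k)
  reads <- check_reads(reads)
  nk <- as.integer(4^k)
  sw <- scan_windows(reads$seq, k)
  code <- sw$code
  if (canonical) code <- pmin(code, rc_code(code, k))
  occurrence <- tabulate(code + 1L, nbins = nk)
  key <- unique((sw$id - 1) * as.double(nk) + code)
  presence <- tabulate(as.integer(key %% nk) + 1L, nbins = nk)
  out <- tibble(kmer = decode_kmer(seq_len(nk) - 1L, k),
                occurrence = occurrence, presence = presence)
  new_kmer_table(out, k = k, n_reads = nrow(reads),
                 n_windows = length(code), canonical = canonical)
}

new_kmer_table <- function(df, k, n_reads, n_windows, canonical) {
  attr(df, "k") <- as.integer(k)
  attr(df, "n_reads") <- as.integer(n_reads)
  attr(df, "n_windows") <- as.integer(n_windows)
  attr(df, "canonical") <- isTRUE(canonical)
  class(df) <- c("kmer_table", class(df))
  df
}

kmer_attr <- function(t, what) {
  attr(t, what) %||%
    abort(sprintf("input lacks the `%s` attribute; pass the result of count_kmers() directly", what))
}

#' Per-read presence fractions of all k-mers
#'
#' The abundance statistic used throughout: the fraction of reads in the
#' sample that contain the k-mer at least once. Bounded in `[0, 1]` and
#' robust to repeats within a read.
#'
#' @param t A `kmer_table` from [count_kmers()].
#' @return The table with an added `fraction` column.
#' @export
kmer_fractions <- function(t) {
  n <- kmer_attr(t, "n_reads")
  if (n == 0) abort("sample has no reads; fractions are undefined",
                    class = "selexkit_empty_error")
  t$fraction <- t$presence / n
  t
}

#' Positional nucleotide composition of a sample
#'
#' A QC summary: per-position frequencies of A/C/G/T across reads of
#' uniform length (run after trimming). `N`s are excluded from the
#' counted bases; positions where nothing was counted are flagged with
#' `n_counted = 0` and `NA` frequencies.
#'
#' @param reads Read tibble with all sequences the same length.
#' @return A tibble of class `positional_model` with columns `position`,
#'   `A`, `C`, `G`, `T` (frequencies summing to 1 per row), `n_counted`.
#' @export
positional_model <- function(reads) {
  reads <- check_reads(reads)
  if (nrow(reads) == 0) abort("no reads", class = "selexkit_empty_error")
  L <- unique(nchar(reads$seq))
  if (length(L) != 1) {
    abort("reads have mixed lengths; trim to a uniform length first (see trim_reads())",
          class = "selexkit_length_error")
  }
  rows <- lapply(seq_len(L), function(i) {
    ch <- factor(substr(reads$seq, i, i), levels = DNA_BASES)
    cnt <- tabulate(ch, nbins = 4L)
    n <- sum(cnt)
    freq <- if (n > 0) cnt / n else rep(NA_real_, 4)
    tibble(position = i, A = freq[1], C = freq[2], G = freq[3], T = freq[4],
           n_counted = n)
  })
  out <- bind_rows(rows)
  class(out) <- c("positional_model", class(out))
  out
}

#' Top-m k-mers by fraction
#'
#' Deterministic ranking: descending fraction, ties broken by ascending
#' encoded integer (equivalently alphabetical order, since A<C<G<T).
#'
#' @param x A `kmer_table` (fractions are computed if absent) or any
#'   tibble with `kmer` and `fraction` columns.
#' @param m Number of k-mers to return.
#' @return A tibble with columns `kmer`, `fraction`, `m` rows.
#' @export
top_kmers <- function(x, m) {
  m <- as.integer(m)
  if (m < 1L) abort("m must be >= 1")
  if (!"fraction" %in% names(x)) {
    if (inherits(x, "kmer_table")) x <- kmer_fractions(x)
    else abort("`x` must have a fraction column or be a kmer_table")
  }
  o <- order(-x$fraction, x$kmer)
  head(tibble(kmer = x$kmer[o], fraction = x$fraction[o]), m)
}
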