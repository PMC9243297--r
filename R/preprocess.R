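# Read pre-processing ahead of k-mer counting: quality tail trim, hard
# trim to the insert length, minimum-length filter, optional clip of a
# constant 5' prefix. Equivalent to running the flexbar step with
# `--post-trim-length 20 --min-read-length 20 --qtrim-threshold 30`.

#' Trimming configuration
#'
#' @param qtrim_threshold Phred threshold for the 3' quality tail trim
#'   (default 30): the maximal run of trailing bases with quality below
#'   this is removed.
#' @param post_trim_length Hard-trim length in bp; the 5'-most
#'   `post_trim_length` bases are kept. Default 20, the insert size of
#'   the library design.
#' @param min_read_length Reads shorter than this after trimming are
#'   rejected (default 20, so survivors are exactly the insert).
#' @param prefix_clip Optional constant 5' sequence removed (exact match
#'   only) before any trimming, for runs whose reads start upstream of
#'   the insert.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(qtrim_threshold = 30L, post_trim_length = 20L,
                        min_read_length = 20L, prefix_clip = NULL) {
  qtrim_threshold <- as.integer(qtrim_threshold)
  post_trim_length <- as.integer(post_trim_length)
  min_read_length <- as.integer(min_read_length)
  if (qtrim_threshold < 0L) abort("qtrim_threshold must be >= 0")
  if (min_read_length < 1L || post_trim_length < min_read_length) {
    abort("need post_trim_length >= min_read_length >= 1")
  }
  if (!is.null(prefix_clip)) {
    prefix_clip <- toupper(prefix_clip)
    check_dna(prefix_clip, allow_n = FALSE, what = "prefix_clip")
  }
  structure(list(qtrim_threshold = qtrim_threshold,
                 post_trim_length = post_trim_length,
                 min_read_length = min_read_length,
                 prefix_clip = prefix_clip),
            class = "trim_config")
}

#' Remove the low-quality 3' tail of each read
#'
#' Tail-trim semantics: the maximal run of 3'-terminal bases whose
#' quality is below `threshold` is removed; the 5' end is untouched.
#' Reads without qualities are returned unchanged.
#'
#' @param reads Read tibble.
#' @param threshold Phred threshold.
#' @return The read tibble with `seq`/`qual` shortened where trimmed.
#' @export
quality_trim_tail <- function(reads, threshold = 30L) {
  reads <- check_reads(reads)
  threshold <- as.integer(threshold)
  if (threshold <= 0L || nrow(reads) == 0) return(reads)
  # Phred q < threshold <=> ASCII char <= 32 + threshold (Phred+33).
  hi <- min(32L + threshold, 126L)
  low_class <- sprintf("[\\x21-\\x%02X]", hi)
  has_q <- !is.na(reads$qual)
  trimmed_q <- sub(paste0(low_class, "+$"), "", reads$qual[has_q], perl = TRUE)
  keep_len <- nchar(trimmed_q)
  reads$qual[has_q] <- trimmed_q
  reads$seq[has_q] <- substr(reads$seq[has_q], 1L, keep_len)
  reads
}

#' Trim reads to the library insert
#'
#' Applies, in order: the optional exact 5' prefix clip, the quality tail
#' trim, and the hard trim keeping the first `post_trim_length` bases;
#' reads left shorter than `min_read_length` are rejected. With the
#' default configuration every surviving read is exactly 20 bp — the
#' library insert.
#'
#' @param reads Read tibble.
#' @param cfg A [trim_config()].
#' @return The tibble of surviving reads. The attribute `trim_summary`
#'   (see [trim_summary()]) records `input`, `passed` and `rejected`
#'   counts, which always satisfy `input == passed + rejected`.
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  stopifnot(inherits(cfg, "trim_config"))
  reads <- check_reads(reads)
  n_in <- nrow(reads)
  if (!is.null(cfg$prefix_clip) && n_in > 0) {
    hit <- startsWith(reads$seq, cfg$prefix_clip)
    off <- nchar(cfg$prefix_clip)
    reads$seq[hit] <- substring(reads$seq[hit], off + 1L)
    hq <- hit & !is.na(reads$qual)
    reads$qual[hq] <- substring(reads$qual[hq], off + 1L)
  }
  reads <- quality_trim_tail(reads, cfg$qtrim_threshold)
  reads$seq <- substr(reads$seq, 1L, cfg$post_trim_length)
  hq <- !is.na(reads$qual)
  reads$qual[hq] <- substr(reads$qual[hq], 1L, cfg$post_trim_length)
  out <- reads[nchar(reads$seq) >= cfg$min_read_length, , drop = FALSE]
  attr(out, "trim_summary") <- tibble(input = n_in, passed = nrow(out),
                                      rejected = n_in - nrow(out))
  out
}

#' @rdname trim_reads
#' @param trimmed Result of [trim_reads()].
#' @export
trim_summary <- function(trimmed) {
  attr(trimmed, "trim_summary") %||%
    abort("no trim_summary attribute; was this produced by trim_reads()?")
}

#' Pre-process a sequence file
#'
#' Reads a FASTA/FASTQ file, applies [trim_reads()], and writes the
#' survivors. The default output format is FASTA (qualities dropped, as
#' in the original pipeline); pass `out_format = "fastq"` to keep them.
#'
#' @param in_path Input file.
#' @param out_path Output file (`.gz` to compress).
#' @param cfg A [trim_config()].
#' @param out_format `"fasta"` (default) or `"fastq"`.
#' @return A one-row tibble with columns `input`, `passed`, `rejected`.
#' @export
preprocess_file <- function(in_path, out_path, cfg = trim_config(),
                            out_format = c("fasta", "fastq")) {
  out_format <- match.arg(out_format)
  reads <- read_seqs(in_path)
  trimmed <- trim_reads(reads, cfg)
  if (out_format == "fasta") trimmed$qual <- NA_character_
  write_seqs(trimmed, out_path, format = out_format)
  trim_summary(trimmed)
}
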