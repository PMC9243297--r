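# Construct arithmetic: primer annealing, in-silico PCR, barcode
# extraction/validation and demultiplexing.

# Enumerate annealing sites of `primer`'s 3'-terminal suffixes on a
# template. N in the template is a wildcard but contributes no pairing
# evidence: a site is valid only if at least `min_anneal` non-N template
# bases pair exactly, and sites are ranked by that count (ties broken by
# longer suffix, then leftmost). This keeps a primer from "annealing"
# inside the random insert of an N-containing template.
find_anneal <- function(primer, template, min_anneal, orientation = c("fw", "rv")) {
  orientation <- match.arg(orientation)
  tv <- strsplit(template, "")[[1]]
  nt <- length(tv)
  np <- nchar(primer)
  fixed_t <- tv != "N"
  if (min(np, nt) < min_anneal) return(NULL)
  hits <- list()
  for (L in seq(min(np, nt), min_anneal, by = -1L)) {
    pat <- substr(primer, np - L + 1L, np)
    if (orientation == "rv") pat <- reverse_complement(pat)
    pv <- strsplit(pat, "")[[1]]
    ns <- nt - L + 1L
    ok <- rep(TRUE, ns)
    score <- integer(ns)
    for (j in seq_len(L)) {
      tj <- tv[seq_len(ns) + j - 1L]
      fj <- fixed_t[seq_len(ns) + j - 1L]
      ok <- ok & (!fj | tj == pv[j])
      score <- score + as.integer(fj)
    }
    s <- which(ok & score >= min_anneal)
    if (length(s)) {
      hits[[length(hits) + 1L]] <-
        tibble(start = s, end = s + L - 1L, suffix_length = L, exact = score[s])
    }
  }
  if (!length(hits)) return(NULL)
  h <- bind_rows(hits)
  best <- max(h$exact)
  h <- h[h$exact == best, , drop = FALSE]
  # Disjoint equally-good windows mean the primer could prime two products.
  if (nrow(h) > 1) {
    h2 <- h[order(h$start), , drop = FALSE]
    if (any(h2$start[-1] > cummax(h2$end)[-nrow(h2)])) {
      abort(sprintf("primer anneals at multiple disjoint sites on the template (%d candidate windows)",
                    nrow(h2)),
            class = "selexkit_pcr_ambiguity")
    }
  }
  h <- h[order(-h$suffix_length, h$start), , drop = FALSE]
  h[1, ]
}

#' In-silico PCR of a template with two flanking primers
#'
#' Locates the longest 3'-terminal suffix of the forward primer matching
#' the template and the longest 3'-terminal suffix of the reverse primer
#' whose reverse complement matches the template, then returns the top
#' strand of the extended duplex: forward 5' extension, annealed template
#' span, reverse complement of the reverse primer's 5' extension. `N`
#' bases in the template act as wildcards and are preserved verbatim in
#' the product, so the design arithmetic can be run on the printed
#' N-containing template: the 63 nt random-library template yields an
#' 83 bp product with the library primers, and re-amplifying that product
#' with the sequencing primers yields 144 bp.
#'
#' Annealing is exact-match (no mismatch tolerance, no thermodynamics);
#' positions opposite template `N`s match any base but do not count
#' towards the `min_anneal` pairing requirement.
#'
#' @param template Template DNA (5'→3' top strand), may contain `N`.
#' @param fw,rv Primer sequences 5'→3' over `{A,C,G,T}`.
#' @param min_anneal Minimum number of exactly paired bases (default 15).
#' @return The product top strand as a character scalar, with an
#'   `anneal` attribute describing both annealing windows.
#' @export
#' @examples
#' p <- in_silico_pcr(random_library_template(),
#'                    "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
#'                    "CTGGAGTTCAGACGTGTGCTCTTCCGATCT")
#' nchar(p) # 83
in_silico_pcr <- function(template, fw, rv, min_anneal = 15L) {
  template <- toupper(template)
  fw <- toupper(fw)
  rv <- toupper(rv)
  check_dna(template, allow_n = TRUE, what = "template")
  check_dna(fw, allow_n = FALSE, what = "fw primer")
  check_dna(rv, allow_n = FALSE, what = "rv primer")
  min_anneal <- as.integer(min_anneal)
  if (min_anneal < 10L) abort("min_anneal must be >= 10")
  a <- find_anneal(fw, template, min_anneal, "fw")
  if (is.null(a)) {
    abort(sprintf("forward primer does not anneal (no site with >= %d paired bases)",
                  min_anneal),
          class = "selexkit_pcr_error")
  }
  b <- find_anneal(rv, template, min_anneal, "rv")
  if (is.null(b)) {
    abort(sprintf("reverse primer does not anneal (no site with >= %d paired bases)",
                  min_anneal),
          class = "selexkit_pcr_error")
  }
  if (a$start > b$start || a$end > b$end) {
    abort("forward primer site is not 5' of the reverse primer site",
          class = "selexkit_pcr_error")
  }
  fw_ext <- substr(fw, 1L, nchar(fw) - a$suffix_length)
  rv_ext <- substr(rv, 1L, nchar(rv) - b$suffix_length)
  product <- paste0(fw_ext,
                    substr(template, a$start, b$end),
                    if (nzchar(rv_ext)) reverse_complement(rv_ext) else "")
  attr(product, "anneal") <- bind_rows(
    mutate(a, primer = "fw", .before = 1),
    mutate(b, primer = "rv", .before = 1)
  )
  product
}

#' Extract the barcode embedded in a primer
#'
#' Given a primer known to have the structure
#' `five_flank + barcode + three_flank`, returns the (non-empty) barcode.
#'
#' @param primer Primer sequence.
#' @param five_flank,three_flank The constant regions surrounding the
#'   barcode.
#' @return The barcode as a character scalar.
#' @export
#' @examples
#' extract_barcode("AAACCCTTTGGG", "AAA", "GGG") # "CCCTTT"
extract_barcode <- function(primer, five_flank, three_flank) {
  i5 <- regexpr(five_flank, primer, fixed = TRUE)
  if (i5 < 0) {
    abort("primer does not contain the stated 5' flank",
          class = "selexkit_structure_error")
  }
  rest_start <- i5 + nchar(five_flank)
  rest <- substr(primer, rest_start, nchar(primer))
  i3 <- regexpr(three_flank, rest, fixed = TRUE)
  if (i3 < 0) {
    abort("primer does not contain the stated 3' flank downstream of the 5' flank",
          class = "selexkit_structure_error")
  }
  if (i3 == 1) {
    abort("no barcode between the stated flanks (flanks are adjacent)",
          class = "selexkit_structure_error")
  }
  substr(rest, 1L, i3 - 1L)
}

#' Construct a barcode table
#'
#' A barcode table maps sample names to sample-identifying DNA barcodes
#' (i7 indexes). All barcodes must have the same length and be unique.
#'
#' @param sample_name Character vector of unique sample names.
#' @param barcode Character vector of DNA barcodes (same length each).
#' @return A tibble of class `barcode_table` with columns `sample_name`,
#'   `barcode`.
#' @export
barcode_table <- function(sample_name, barcode) {
  if (length(sample_name) != length(barcode)) {
    abort("sample_name and barcode must have the same length")
  }
  barcode <- toupper(barcode)
  check_dna(barcode, allow_n = FALSE, what = "barcode")
  if (length(unique(nchar(barcode))) > 1) {
    abort("all barcodes must have the same length",
          class = "selexkit_barcode_error")
  }
  if (anyDuplicated(barcode)) {
    abort(sprintf("duplicate barcode '%s'", barcode[duplicated(barcode)][1]),
          class = "selexkit_barcode_error")
  }
  if (anyDuplicated(sample_name)) {
    abort("sample names must be unique", class = "selexkit_barcode_error")
  }
  out <- tibble(sample_name = as.character(sample_name), barcode = barcode)
  class(out) <- c("barcode_table", class(out))
  out
}

#' Read a barcode table from a 2-column TSV (sample name, barcode)
#' @param path Path to the TSV file (no header).
#' @return A [barcode_table()].
#' @export
read_barcode_table <- function(path) {
  x <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(x) < 2) abort("barcode TSV must have two columns: name, barcode")
  barcode_table(x[[1]], x[[2]])
}

pairwise_hamming <- function(x) {
  n <- length(x)
  m <- do.call(rbind, strsplit(x, ""))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Validate a barcode set
#'
#' Checks the design constraints on a set of sample barcodes: all entries
#' the same length, minimum pairwise Hamming distance (the design calls
#' for at least two mismatches between any pair), and per-position base
#' composition (reported for a homogeneity check, not thresholded).
#'
#' @param table A [barcode_table()] with at least 2 entries.
#' @return A list of class `barcode_report` with elements `n`, `length`,
#'   `min_pairwise_hamming` and `per_position_base_counts` (a tibble with
#'   columns `position`, `A`, `C`, `G`, `T`).
#' @export
validate_barcode_set <- function(table) {
  if (!all(c("sample_name", "barcode") %in% names(table))) {
    abort("`table` must have columns sample_name and barcode")
  }
  bc <- table$barcode
  if (length(bc) < 2) abort("need at least 2 barcodes to validate a set")
  if (length(unique(nchar(bc))) > 1) {
    abort("barcodes have unequal lengths", class = "selexkit_barcode_error")
  }
  L <- nchar(bc[1])
  d <- pairwise_hamming(bc)
  counts <- lapply(seq_len(L), function(i) {
    ch <- factor(substr(bc, i, i), levels = DNA_BASES)
    as.list(table(ch))
  })
  ppc <- bind_rows(lapply(counts, as_tibble))
  ppc <- mutate(ppc, position = seq_len(L), .before = 1)
  structure(
    list(n = length(bc), length = L,
         min_pairwise_hamming = min(d[upper.tri(d)]),
         per_position_base_counts = ppc),
    class = "barcode_report"
  )
}

#' @export
print.barcode_report <- function(x, ...) {
  cat(sprintf("<barcode_report> %d barcodes of length %d; min pairwise Hamming distance %d\n",
              x$n, x$length, x$min_pairwise_hamming))
  cat("per-position base counts:\n")
  print(x$per_position_base_counts)
  invisible(x)
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the unique barcode within `max_mismatch`
#' mismatches of its observed index. Reads matching no barcode, or more
#' than one, are left unassigned, so the partition is exhaustive and
#' disjoint. With the design's minimum pairwise barcode distance of 2,
#' one-mismatch assignment cannot be guaranteed unambiguous, hence the
#' default `max_mismatch = 0`.
#'
#' @param reads Read tibble. In `"tag"` mode the observed index is taken
#'   from a `barcode` column (see [illumina_index()]); in `"suffix"` mode
#'   from the last `L` bases of the read, where `L` is the barcode length.
#' @param table A [barcode_table()].
#' @param max_mismatch 0 (default) or 1 mismatches tolerated.
#' @param barcode_from `"tag"` or `"suffix"`.
#' @return The read tibble with an added `sample_name` column
#'   (`NA` for unassigned reads).
#' @export
demultiplex <- function(reads, table, max_mismatch = 0L,
                        barcode_from = c("tag", "suffix")) {
  barcode_from <- match.arg(barcode_from)
  reads <- check_reads(reads)
  if (!max_mismatch %in% c(0L, 1L)) abort("max_mismatch must be 0 or 1")
  bc <- table$barcode
  L <- nchar(bc[1])
  obs <- if (barcode_from == "tag") {
    if (!"barcode" %in% names(reads)) {
      abort("barcode_from = \"tag\" requires a `barcode` column; see illumina_index()")
    }
    toupper(reads$barcode)
  } else {
    substr(reads$seq, pmax(1L, nchar(reads$seq) - L + 1L), nchar(reads$seq))
  }
  n <- length(obs)
  if (n == 0) {
    reads$sample_name <- character()
    return(reads)
  }
  dist <- matrix(0L, n, length(bc))
  for (b in seq_along(bc)) {
    bv <- strsplit(bc[b], "")[[1]]
    mism <- as.integer(nchar(obs) != L) * L # wrong-length index never matches
    for (j in seq_len(L)) {
      mism <- mism + as.integer(substr(obs, j, j) != bv[j])
    }
    dist[, b] <- mism
  }
  within <- dist <= max_mismatch
  nhit <- rowSums(within)
  assigned <- ifelse(nhit == 1L, apply(within, 1, function(z) which(z)[1]), NA_integer_)
  reads$sample_name <- table$sample_name[assigned]
  reads
}

#' Extract the index field from an Illumina-style read header
#'
#' Read headers written by [simulate_dataset()] (and by Illumina
#' instruments) end in `...:<index>`; this pulls that final field into a
#' `barcode` column for [demultiplex()]'s tag mode.
#'
#' @param reads Read tibble.
#' @return `reads` with a `barcode` column added.
#' @export
illumina_index <- function(reads) {
  reads <- check_reads(reads)
  reads$barcode <- sub(".*:", "", reads$id)
  reads
}

#' Demultiplex a sequence file into per-sample FASTQ files
#'
#' File-level wrapper around [demultiplex()]: writes one
#' `<sample_name>.fastq` per barcode plus `unassigned.fastq` into
#' `out_dir`.
#'
#' @inheritParams demultiplex
#' @param in_path Input FASTQ path.
#' @param out_dir Output directory (created if needed).
#' @param gzip Compress outputs.
#' @return A tibble with columns `sample_name`, `file`, `n_reads`
#'   (including the unassigned bucket).
#' @export
demux_files <- function(in_path, table, out_dir, max_mismatch = 0L,
                        barcode_from = c("tag", "suffix"), gzip = FALSE) {
  barcode_from <- match.arg(barcode_from)
  reads <- read_seqs(in_path, format = "fastq")
  if (barcode_from == "tag") reads <- illumina_index(reads)
  reads <- demultiplex(reads, table, max_mismatch, barcode_from)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  groups <- c(table$sample_name, "unassigned")
  res <- lapply(groups, function(s) {
    sel <- if (s == "unassigned") is.na(reads$sample_name) else
      !is.na(reads$sample_name) & reads$sample_name == s
    f <- file.path(out_dir, paste0(s, ext))
    n <- write_seqs(reads[sel, c("id", "seq", "qual")], f, format = "fastq")
    tibble(sample_name = s, file = f, n_reads = n)
  })
  bind_rows(res)
}
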