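# The oligonucleotide set of the SALL4 ZFC4 HT-SELEX design: a 63 nt
# single-stranded template carrying a 20 bp random insert between constant
# flanks, the two library amplification primers, and the Illumina
# sequencing-library primers (one forward primer plus 21 reverse primers,
# each embedding a unique 8 bp i7 barcode).

RANDOM_TEMPLATE_5P <- "TACACGACGCTCTTCCGATCT"
RANDOM_TEMPLATE_3P <- "AGATCGGAAGAGCACACGTCTG"
LIBRARY_FW <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
LIBRARY_RV <- "CTGGAGTTCAGACGTGTGCTCTTCCGATCT"
SEQLIB_FW <- "AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGC"
SEQLIB_RV_5P_FLANK <- "CAAGCAGAAGACGGCATACGAGAT"
SEQLIB_RV_3P_FLANK <- "GTGACTGGAGTTCAGACGTGTGCTCT"

SEQLIB_RV_BARCODES <- c(
  "CCAAGTCC", "CAGTGGAT", "CTAGCTTG", "GAGTCCAA", "TCCGGATT", "AAGGTACC",
  "GGAACGTT", "GGCCTCAT", "ATCTTAGT", "CTTCACGG", "TCCTGTAA", "CCTCGGTA",
  "ATGAGGCT", "GCAGAATC", "TGTCGTAG", "TAGAGCGC", "GGTTCACC", "CATTGTTG",
  "ACGCCGCA", "GTATTATG", "AGCGAGCT"
)

#' The single-stranded random-library template
#'
#' A 63 nt oligonucleotide: 21 nt constant 5' flank, a 20 base random
#' insert (written as `N`), and a 22 nt constant 3' flank. Amplification
#' with the `Library FW` / `Library RV` primers yields the 83 bp
#' double-stranded cycle-0 SELEX library.
#'
#' @param insert Optional concrete 20-mer (or any `{A,C,G,T}` string of the
#'   insert length) replacing the `N` run, e.g. to build a specific
#'   molecule of the library.
#' @return A character scalar.
#' @export
#' @examples
#' nchar(random_library_template()) # 63
random_library_template <- function(insert = NULL) {
  if (is.null(insert)) {
    insert <- strrep("N", 20L)
  } else {
    check_dna(insert, allow_n = FALSE, what = "insert")
  }
  paste0(RANDOM_TEMPLATE_5P, insert, RANDOM_TEMPLATE_3P)
}

#' The HT-SELEX oligonucleotide set
#'
#' All oligonucleotides of the design as a tibble: the three identical
#' random-library templates (independent syntheses used as replicate
#' libraries), the library amplification primers, and the sequencing
#' library primers including the 21 barcoded reverse primers.
#'
#' @return A tibble with columns `name`, `sequence`, `role`.
#' @export
ht_selex_oligos <- function() {
  rv <- paste0(SEQLIB_RV_5P_FLANK, SEQLIB_RV_BARCODES, SEQLIB_RV_3P_FLANK)
  tibble(
    name = c(paste("Random library", 1:3), "Library FW", "Library RV",
             "Seqlib FW", paste("Seqlib RV", seq_along(rv))),
    sequence = c(rep(random_library_template(), 3), LIBRARY_FW,
                 LIBRARY_RV, SEQLIB_FW, rv),
    role = c(rep("template", 3), rep("library_primer", 2),
             "seqlib_primer", rep("seqlib_primer", length(rv)))
  )
}

#' Barcode table of the 21 sequencing reverse primers
#'
#' Extracts the 8 bp i7 barcode embedded in each `Seqlib RV` primer
#' (between the P7 flank and the constant 3' annealing region) and pairs
#' it with a sample name.
#'
#' @param sample_names Names to assign, one per primer; defaults to
#'   `RV01..RV21`.
#' @return A barcode table tibble (`sample_name`, `barcode`), see
#'   [barcode_table()].
#' @export
seqlib_barcodes <- function(sample_names = sprintf("RV%02d", seq_along(SEQLIB_RV_BARCODES))) {
  primers <- paste0(SEQLIB_RV_5P_FLANK, SEQLIB_RV_BARCODES, SEQLIB_RV_3P_FLANK)
  bc <- vapply(primers, extract_barcode,
               five_flank = SEQLIB_RV_5P_FLANK,
               three_flank = SEQLIB_RV_3P_FLANK,
               FUN.VALUE = character(1), USE.NAMES = FALSE)
  barcode_table(sample_names, bc)
}

#' Describe a library construct
#'
#' A library construct is the fixed architecture `5' flank + random insert
#' + 3' flank` shared by every molecule of a SELEX library.
#'
#' @param five_prime_flank,three_prime_flank Constant flanks (non-empty DNA).
#' @param insert_length Length of the random insert in bp (> 0).
#' @param description Free-text label.
#' @return A list of class `library_construct`.
#' @export
library_construct <- function(five_prime_flank, insert_length, three_prime_flank,
                              description = "") {
  check_dna(five_prime_flank, allow_n = FALSE, what = "five_prime_flank")
  check_dna(three_prime_flank, allow_n = FALSE, what = "three_prime_flank")
  if (!nzchar(five_prime_flank) || !nzchar(three_prime_flank)) {
    abort("construct flanks must be non-empty")
  }
  insert_length <- as.integer(insert_length)
  if (is.na(insert_length) || insert_length <= 0) {
    abort("insert_length must be a positive integer")
  }
  structure(
    list(five_prime_flank = five_prime_flank, insert_length = insert_length,
         three_prime_flank = three_prime_flank, description = description),
    class = "library_construct"
  )
}

#' @export
print.library_construct <- function(x, ...) {
  cat(sprintf("<library_construct> %s\n", x$description))
  cat(sprintf("  5' %s | %d bp random insert | %s 3'\n",
              x$five_prime_flank, x$insert_length, x$three_prime_flank))
  invisible(x)
}

#' @rdname library_construct
#' @export
random_library_construct <- function() {
  library_construct(RANDOM_TEMPLATE_5P, 20L, RANDOM_TEMPLATE_3P,
                    description = "20 bp random-insert SELEX library template")
}

# Top strand of the final 144 bp sequencing construct downstream of the
# insert: the constant 3' flank, the reverse complement of the Library RV
# 5' tail plus Seqlib RV annealing overhang, then the reverse complements
# of the i7 barcode and the P7 flank. This is what a Read 1 sequencer call
# walks into once it has crossed the 20 bp insert.
post_insert_readthrough <- function(barcode) {
  paste0(RANDOM_TEMPLATE_3P,
         reverse_complement(substr(SEQLIB_RV_3P_FLANK, 1L, 12L)),
         reverse_complement(barcode),
         reverse_complement(SEQLIB_RV_5P_FLANK))
}
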