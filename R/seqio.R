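# Sequence and metadata IO. Reads live in tidy tibbles with columns
# id / seq / qual; qualities are Phred+33 strings (NA for FASTA input).

guess_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(fa|fasta)$", p)) return("fasta")
  if (grepl("\\.(fq|fastq)$", p)) return("fastq")
  abort(sprintf("cannot infer sequence format from extension of '%s'", path),
        class = "selexkit_format_error")
}

#' Read a FASTA or FASTQ file into a read tibble
#'
#' Sequences are uppercased on input and must stay within the
#' `{A,C,G,T,N}` alphabet; gzip compression is handled transparently.
#' FASTQ qualities are kept as Phred+33 strings in the `qual` column
#' (`NA` for FASTA records); use [phred_scores()] for integer scores.
#'
#' @param path Path to a `.fa/.fasta/.fq/.fastq` file, optionally `.gz`.
#' @param format `"auto"` (default, from the extension), `"fasta"` or
#'   `"fastq"`.
#' @return A tibble with columns `id`, `seq`, `qual`, in file order.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path), class = "selexkit_io_error")
  }
  if (format == "auto") format <- guess_format(path)
  reads <- if (format == "fasta") read_fasta(path) else read_fastq(path)
  reads$seq <- toupper(reads$seq)
  check_dna(reads$seq, allow_n = TRUE, what = sprintf("read in '%s'", path))
  reads
}

read_fasta <- function(path) {
  # Zero-record files: readDNAStringSet() is unhappy with headerless input.
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first)) return(new_read_tibble(character(), character()))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  new_read_tibble(names(x), as.character(x))
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(new_read_tibble(character(), character()))
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("FASTQ file '%s' has %d lines, not a multiple of 4",
                  path, length(lines)),
          class = "selexkit_parse_error")
  }
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]; seq <- lines[i + 1L]; plus <- lines[i + 2L]; qual <- lines[i + 3L]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d in '%s' (missing '@' or '+' line)",
                  bad[1], path),
          class = "selexkit_parse_error")
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    abort(sprintf(
      "malformed FASTQ record %d in '%s': sequence length %d but %d quality symbols",
      bad[1], path, nchar(seq[bad[1]]), nchar(qual[bad[1]])),
      class = "selexkit_parse_error")
  }
  new_read_tibble(substring(hdr, 2L), seq, qual)
}

#' Write reads to FASTA or FASTQ
#'
#' Records are written in the standard 2-line FASTA / 4-line FASTQ layout;
#' a `.gz` suffix triggers gzip compression. FASTQ output requires every
#' read to carry qualities.
#'
#' @param reads Read tibble (columns `id`, `seq`, optional `qual`).
#' @inheritParams read_seqs
#' @return Invisibly, the number of records written.
#' @export
write_seqs <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  reads <- check_reads(reads, need_qual = identical(format, "fastq"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0) {
    out <- if (format == "fasta") {
      as.vector(rbind(paste0(">", reads$id), reads$seq))
    } else {
      as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
    }
    writeLines(out, con)
  } else {
    writeLines(character(), con)
  }
  invisible(n)
}

#' Read an HT-SELEX sample metadata sheet
#'
#' The sheet is tab-separated with a header naming (case-insensitively) the
#' four columns `Samplename`, `library`, `protein`, `cycle`; any extra
#' columns are preserved untouched. A `protein` value of `"None"` (any
#' case) marks a no-protein negative control and is normalised to `"None"`.
#'
#' @param path Path to the TSV sheet.
#' @return A tibble with columns `sample_name`, `library`, `protein`,
#'   `cycle` (integer), `is_control` (logical), plus any extra columns,
#'   one row per sample in sheet order.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path), class = "selexkit_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort("metadata sheet is empty (no header line)", class = "selexkit_parse_error")
  }
  split_tab <- function(x) strsplit(x, "\t", fixed = TRUE)
  hdr <- trimws(split_tab(lines[1])[[1]])
  required <- c("samplename", "library", "protein", "cycle")
  idx <- match(required, tolower(hdr))
  if (anyNA(idx)) {
    abort(sprintf("metadata sheet is missing required column(s): %s",
                  paste(required[is.na(idx)], collapse = ", ")),
          class = "selexkit_parse_error")
  }
  body <- lines[-1]
  if (!length(body)) {
    out <- tibble(sample_name = character(), library = character(),
                  protein = character(), cycle = integer(),
                  is_control = logical())
    return(out)
  }
  cells <- split_tab(body)
  nfld <- lengths(cells)
  if (any(nfld < length(hdr))) {
    r <- which(nfld < length(hdr))[1]
    abort(sprintf("metadata row %d has %d fields but the header has %d",
                  r, nfld[r], length(hdr)),
          class = "selexkit_parse_error")
  }
  mat <- do.call(rbind, lapply(cells, function(x) trimws(x[seq_along(hdr)])))
  cyc_chr <- mat[, idx[4]]
  cyc <- suppressWarnings(as.integer(cyc_chr))
  bad <- which(is.na(cyc) | as.character(cyc) != cyc_chr)
  if (length(bad)) {
    abort(sprintf("metadata row %d: cycle '%s' is not a non-negative integer",
                  bad[1], cyc_chr[bad[1]]),
          class = "selexkit_parse_error")
  }
  if (any(cyc < 0)) {
    abort(sprintf("metadata row %d: cycle must be >= 0", which(cyc < 0)[1]),
          class = "selexkit_parse_error")
  }
  sample_name <- mat[, idx[1]]
  if (anyDuplicated(sample_name)) {
    dup <- sample_name[duplicated(sample_name)][1]
    abort(sprintf("duplicate sample name '%s' in metadata sheet (row %d)",
                  dup, which(duplicated(sample_name))[1]),
          class = "selexkit_parse_error")
  }
  protein <- mat[, idx[3]]
  is_control <- tolower(protein) == "none"
  protein[is_control] <- "None"
  out <- tibble(sample_name = sample_name, library = mat[, idx[2]],
                protein = protein, cycle = cyc, is_control = is_control)
  extra <- setdiff(seq_along(hdr), idx)
  for (j in extra) out[[hdr[j]]] <- mat[, j]
  out
}

#' Write a sample metadata sheet
#'
#' Inverse of [read_sample_sheet()]; emits the canonical header
#' `Samplename library protein cycle` (tab-separated).
#'
#' @param meta Tibble with columns `sample_name`, `library`, `protein`,
#'   `cycle`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(meta, path) {
  stopifnot(all(c("sample_name", "library", "protein", "cycle") %in% names(meta)))
  lines <- c(
    paste(c("Samplename", "library", "protein", "cycle"), collapse = "\t"),
    paste(meta$sample_name, meta$library, meta$protein, meta$cycle, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
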