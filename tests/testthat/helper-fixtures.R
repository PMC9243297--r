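# Fixture builders and independent oracles shared across tests.

# Random reads with optional N contamination and qualities.
random_read_tbl <- function(n, len = 20, seed = 1, with_qual = TRUE,
                            n_rate = 0, var_len = FALSE) {
  withr::with_seed(seed, {
    lens <- if (var_len) sample(seq(8, len), n, replace = TRUE) else rep(len, n)
    seqs <- vapply(lens, function(L) {
      b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (n_rate > 0) {
        hit <- runif(L) < n_rate
        b[hit] <- "N"
      }
      paste(b, collapse = "")
    }, character(1))
    qual <- if (with_qual) {
      vapply(lens, function(L) {
        intToUtf8(sample(33:73, L, replace = TRUE), multiple = FALSE)
      }, character(1))
    } else {
      NA_character_
    }
    tibble::tibble(id = sprintf("read%04d", seq_len(n)), seq = seqs, qual = qual)
  })
}

# Build a read with explicit integer qualities.
read_with_quals <- function(seq, quals, id = "r1") {
  stopifnot(nchar(seq) == length(quals))
  tibble::tibble(id = id, seq = seq,
                 qual = intToUtf8(as.integer(quals) + 33L, multiple = FALSE))
}

# Independent k-mer counting oracle: plain substring scan with string
# tallies, no integer encoding. Returns vectors aligned with the
# alphabetical (= encoding) order of all 4^k k-mers.
oracle_count_kmers <- function(seqs, k, canonical = FALSE) {
  all_kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                      stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                          1, paste, collapse = ""))
  occ <- stats::setNames(integer(length(all_kmers)), all_kmers)
  pres <- occ
  n_windows <- 0L
  rc1 <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    words <- character(0)
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      if (canonical) {
        w2 <- rc1(w)
        if (w2 < w) w <- w2
      }
      occ[w] <- occ[w] + 1L
      n_windows <- n_windows + 1L
      words <- c(words, w)
    }
    for (w in unique(words)) pres[w] <- pres[w] + 1L
  }
  list(kmer = all_kmers, occurrence = unname(occ), presence = unname(pres),
       n_windows = n_windows)
}

# Definitional Spearman oracle: average ranks, explicit Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

write_temp_fastq <- function(reads, ext = ".fastq") {
  f <- tempfile(fileext = ext)
  selexkit::write_seqs(reads, f, format = "fastq")
  f
}

# The 6-row example metadata sheet: three cycle-0 no-protein rows and
# three cycle-6 protein rows.
example_sheet_lines <- function() {
  c("Samplename\tlibrary\tprotein\tcycle",
    "RV01\tlib1\tNone\t0",
    "RV02\tlib2\tNone\t0",
    "RV03\tlib3\tNone\t0",
    "RV04\tlib1\tZFC4\t6",
    "RV05\tlib2\tZFC4\t6",
    "RV06\tlib3\tZFC4\t6")
}
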