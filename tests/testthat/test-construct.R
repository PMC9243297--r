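# Construct arithmetic: in-silico PCR, barcode extraction/validation,
# demultiplexing.

oligo <- function(name) {
  o <- ht_selex_oligos()
  o$sequence[match(name, o$name)]
}

test_that("library PCR of the random template gives the 83 bp product with the N insert intact", {
  p <- in_silico_pcr(random_library_template(), oligo("Library FW"),
                     oligo("Library RV"))
  expect_equal(nchar(p), 83)
  expect_match(p, "N{20}")
  expect_false(grepl("N", gsub("N{20}", "", p))) # flanks fully concrete
})

test_that("sequencing-library PCR of a concrete 83 bp product gives 144 bp", {
  ins <- paste(rep(c("A", "C", "G", "T"), 5), collapse = "")
  p83 <- in_silico_pcr(random_library_template(ins), oligo("Library FW"),
                       oligo("Library RV"))
  expect_equal(nchar(p83), 83)
  p144 <- in_silico_pcr(p83, oligo("Seqlib FW"), oligo("Seqlib RV 1"))
  expect_equal(nchar(p144), 144)
  expect_true(grepl(ins, p144, fixed = TRUE))
  # re-amplifying the product with the same primers is a fixed point
  expect_equal(as.character(in_silico_pcr(p144, oligo("Seqlib FW"),
                                          oligo("Seqlib RV 1"))),
               as.character(p144))
})

test_that("identity PCR: fully annealing primers reproduce the template", {
  fw <- "ACGTACGTACGTACGTACGT"
  rv_target <- "TTTTGGGGCCCCAAAATTTT"
  template <- paste0(fw, "CCATGG", rv_target)
  p <- in_silico_pcr(template, fw, reverse_complement(rv_target))
  expect_equal(as.character(p), template)
})

test_that("product length law: |product| = |fw ext| + span + |rv ext|", {
  withr::with_seed(5, {
    for (i in 1:10) {
      core_len <- sample(40:80, 1)
      core <- paste(sample(c("A", "C", "G", "T"), core_len, replace = TRUE),
                    collapse = "")
      fw_ext <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), replace = TRUE),
                      collapse = "")
      rv_ext <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), replace = TRUE),
                      collapse = "")
      fw <- paste0(fw_ext, substr(core, 1, 18))
      rv <- paste0(rv_ext, reverse_complement(substr(core, core_len - 17, core_len)))
      p <- tryCatch(in_silico_pcr(core, fw, rv),
                    selexkit_pcr_ambiguity = function(e) NULL)
      if (is.null(p)) next # random core happened to contain a second site
      expect_equal(nchar(p), nchar(fw_ext) + core_len + nchar(rv_ext))
    }
  })
})

test_that("PCR failure modes are classed errors", {
  template <- random_library_template()
  expect_error(in_silico_pcr(template, strrep("G", 20), oligo("Library RV")),
               "does not anneal", class = "selexkit_pcr_error")
  # fw site 3' of rv site -> orientation error
  fw <- "ACGTACGTACGTACGTACGT"
  rv_target <- "TTTTGGGGCCCCAAAATTTT"
  template2 <- paste0(rv_target, "CCATGG", fw)
  expect_error(in_silico_pcr(template2, fw, reverse_complement(rv_target)),
               "not 5'", class = "selexkit_pcr_error")
  # two disjoint annealing sites -> ambiguity
  site <- "ACGTACGTACGTACGTACGT"
  template3 <- paste0(site, strrep("C", 30), site)
  expect_error(in_silico_pcr(template3, site, reverse_complement(strrep("C", 20))),
               class = "selexkit_pcr_ambiguity")
})

test_that("reverse_complement is an involution and maps N to N", {
  withr::with_seed(8, {
    seqs <- replicate(25, paste(sample(c("A", "C", "G", "T", "N"),
                                       sample(1:30, 1), replace = TRUE),
                                collapse = ""))
  })
  expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
  expect_equal(reverse_complement("ACGTN"), "NACGT")
})

test_that("barcode extraction recovers CCAAGTCC from the first sequencing primer", {
  bc <- extract_barcode(oligo("Seqlib RV 1"),
                        "CAAGCAGAAGACGGCATACGAGAT",
                        "GTGACTGGAGTTCAGACGTGTGCTCT")
  expect_equal(bc, "CCAAGTCC")
  expect_error(extract_barcode("AAACCC", "AAA", "GGG"),
               class = "selexkit_structure_error")
  expect_error(extract_barcode("AAAGGG", "AAA", "GGG"),
               class = "selexkit_structure_error") # flanks adjacent
})

test_that("the 21 built-in barcodes are unique, 8 bp, and >= 2 mismatches apart", {
  bt <- seqlib_barcodes()
  expect_equal(nrow(bt), 21)
  expect_equal(unique(nchar(bt$barcode)), 8L)
  expect_equal(anyDuplicated(bt$barcode), 0L)
  rep <- validate_barcode_set(bt)
  expect_gte(rep$min_pairwise_hamming, 2)
  # per-position composition report covers every base at every position
  counts <- rep$per_position_base_counts
  expect_equal(nrow(counts), 8)
  expect_true(all(rowSums(counts[c("A", "C", "G", "T")]) == 21))
})

test_that("barcode table invariants and small Hamming cases", {
  expect_error(barcode_table(c("a", "b"), c("ACGT", "ACGT")),
               class = "selexkit_barcode_error")
  expect_error(barcode_table(c("a", "b"), c("ACGT", "ACG")),
               class = "selexkit_barcode_error")
  rep <- validate_barcode_set(barcode_table(c("a", "b"), c("AAAA", "AAAT")))
  expect_equal(rep$min_pairwise_hamming, 1)
})

test_that("demultiplex assigns exact matches and leaves ambiguity unassigned", {
  bt <- seqlib_barcodes()
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = rep(strrep("A", 20), 3),
    qual = NA_character_,
    barcode = c("CCAAGTCC", "NNNNNNNN", "CCAAGTCG")
  )
  d0 <- demultiplex(reads, bt, max_mismatch = 0)
  expect_equal(d0$sample_name, c("RV01", NA, NA))
  d1 <- demultiplex(reads, bt, max_mismatch = 1)
  expect_equal(d1$sample_name[1:2], c("RV01", NA))
  expect_equal(d1$sample_name[3], "RV01") # distance 1 from a single barcode

  # a tag equidistant (1 mismatch) from two barcodes stays unassigned
  bt2 <- barcode_table(c("s1", "s2"), c("AAAA", "AATT"))
  amb <- tibble::tibble(id = "x", seq = "ACGT", qual = NA, barcode = "AATA")
  expect_true(is.na(demultiplex(amb, bt2, max_mismatch = 1)$sample_name))
})

test_that("demultiplex partitions reads exhaustively (suffix mode included)", {
  bt <- seqlib_barcodes()
  withr::with_seed(21, {
    n <- 300
    bcs <- sample(c(bt$barcode, "GGGGGGGG"), n, replace = TRUE)
    reads <- tibble::tibble(
      id = sprintf("r%d", 1:n),
      seq = paste0(random_read_tbl(n, len = 12, seed = 22, with_qual = FALSE)$seq,
                   bcs),
      qual = NA_character_
    )
  })
  d <- demultiplex(reads, bt, max_mismatch = 0, barcode_from = "suffix")
  counts <- table(d$sample_name, useNA = "always")
  expect_equal(sum(counts), n) # exhaustive + disjoint partition
  expect_equal(unname(counts[is.na(names(counts))]), sum(bcs == "GGGGGGGG"))
  for (s in names(counts)[!is.na(names(counts))]) {
    expect_equal(unname(counts[s]), sum(bcs == bt$barcode[bt$sample_name == s]))
  }
})
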