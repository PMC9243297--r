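# Enrichment: A/T categories, fold-change arithmetic, dataset pairing,
# category summaries.

make_table <- function(presence, n_reads, k = 5) {
  nk <- as.integer(4^k)
  stopifnot(length(presence) == nk)
  df <- tibble::tibble(kmer = selexkit::decode_kmer(0:(nk - 1), k),
                       occurrence = presence, presence = presence)
  selexkit:::new_kmer_table(df, k = k, n_reads = n_reads,
                            n_windows = sum(presence), canonical = FALSE)
}

test_that("at_category counts A/T letters and partitions all 5-mers 6 ways", {
  expect_equal(at_category(c("ATATA", "GCGCG", "ACGTA")), c(5L, 0L, 3L))
  cat5 <- at_category(decode_kmer(0:1023, 5))
  tab <- table(cat5)
  expect_equal(length(tab), 6)
  expect_equal(unname(c(tab)), choose(5, 0:5) * 32)
  expect_equal(sum(tab), 4^5)
})

test_that("fold change follows the pseudocounted ratio exactly", {
  k1 <- make_table(rep(10L, 1024), n_reads = 100)
  s1 <- make_table(rep(c(30L, 10L), c(1, 1023)), n_reads = 100)
  fc <- fold_change(s1, k1, pseudocount = 1)
  expect_equal(fc$fold_change[1], (31 / 101) / (11 / 101))
  expect_equal(fc$fold_change[2], 1)

  # sample vs itself is identically 1
  self <- fold_change(s1, s1)
  expect_true(all(self$fold_change == 1))

  # absent from both with pseudocount: FC = 1 (same n)
  z <- make_table(rep(0L, 1024), n_reads = 50)
  expect_true(all(fold_change(z, z, pseudocount = 1)$fold_change == 1))

  # zero-handling guard
  expect_error(fold_change(s1, z, pseudocount = 0),
               class = "selexkit_division_error")
  # mismatched k
  k3 <- make_table(rep(1L, 64), n_reads = 10, k = 3)
  expect_error(fold_change(s1, k3), class = "selexkit_mismatch_error")
})

test_that("fold change is invariant under proportional rescaling, up to O(a/n)", {
  withr::with_seed(51, pres <- as.integer(rpois(1024, 40)))
  small_s <- make_table(pres, n_reads = 200)
  small_r <- make_table(rev(pres), n_reads = 200)
  big_s <- make_table(pres * 10L, n_reads = 2000)
  big_r <- make_table(rev(pres) * 10L, n_reads = 2000)
  fc_small <- fold_change(small_s, small_r)$fold_change
  fc_big <- fold_change(big_s, big_r)$fold_change
  expect_equal(fc_big, fc_small, tolerance = 1 / 200 * 5)
})

test_that("the 21-sample design pairs every sample to its library-matched cycle 0", {
  meta <- tibble::tibble(
    sample_name = sprintf("RV%02d", 1:21),
    library = rep(sprintf("lib%d", 1:3), 7),
    protein = c(rep("None", 3),
                rep(c("ZFC4", "ZFC4", "ZFC4", "None", "None", "None"), 3)),
    cycle = c(rep(0L, 3), rep(c(1L, 3L, 6L), each = 6))
  )
  withr::with_seed(52, {
    tables <- lapply(seq_len(21), function(i) {
      make_table(as.integer(rpois(1024, 30)), n_reads = 500)
    })
  })
  names(tables) <- meta$sample_name
  e <- enrich_dataset(tables, meta)
  expect_s3_class(e, "selex_enrichment")
  expect_equal(length(unique(e$sample_name)), 18) # all but the 3 cycle-0s
  expect_equal(nrow(e), 18 * 1024)
  ref_by_lib <- c(lib1 = "RV01", lib2 = "RV02", lib3 = "RV03")
  expect_equal(e$reference_sample,
               unname(ref_by_lib[e$library])) # matched-library pairing
  expect_true(all(e$fold_change > 0))
  expect_equal(unique(e$at_category[e$kmer == "ATATA"]), 5L)

  # controls are present as their own rows, never subtracted
  expect_equal(sum(e$is_control), 9 * 1024)

  # cycle-0-only dataset -> empty enrichment
  e0 <- enrich_dataset(tables[1:3], meta[1:3, ])
  expect_equal(nrow(e0), 0)

  # orphan sample without a cycle-0 reference is named in the error
  expect_error(enrich_dataset(tables[c(1, 2, 6)], meta[c(1, 2, 6), ]),
               "RV06", class = "selexkit_reference_error")
})

test_that("pooled cycle-0 pairing uses the summed reference", {
  meta <- tibble::tibble(sample_name = c("c0a", "c0b", "s1"),
                         library = c("lib1", "lib2", "lib1"),
                         protein = c("None", "None", "P"), cycle = c(0L, 0L, 2L))
  tables <- list(c0a = make_table(rep(5L, 1024), 100),
                 c0b = make_table(rep(15L, 1024), 100),
                 s1 = make_table(rep(30L, 1024), 100))
  e <- enrich_dataset(tables, meta,
                      enrichment_config(pairing = "pooled_cycle0"))
  expect_equal(unique(e$reference_sample), "pooled_cycle0")
  expect_equal(e$fold_change[1], ((30 + 1) / 101) / ((20 + 1) / 201))
})

test_that("category summary averages within libraries then across them", {
  meta <- tibble::tibble(sample_name = c("c1", "c2", "p1", "p2"),
                         library = c("lib1", "lib2", "lib1", "lib2"),
                         protein = c("None", "None", "P", "P"),
                         cycle = c(0L, 0L, 1L, 1L))
  withr::with_seed(53, pres <- as.integer(rpois(1024, 25)))
  tables <- list(c1 = make_table(pres, 300), c2 = make_table(pres, 300),
                 p1 = make_table(pres + 5L, 300), p2 = make_table(pres + 5L, 300))
  e <- enrich_dataset(tables, meta)
  s <- summarize_by_category(e)
  expect_equal(nrow(s), 6)
  expect_equal(unique(s$n_libraries), 2L)
  # identical replicates -> zero dispersion
  expect_true(all(s$sd_fc == 0))
  # hand-check one category mean against a direct computation
  cat0 <- e$fold_change[e$at_category == 0 & e$library == "lib1"]
  expect_equal(s$mean_fc[s$at_category == 0], mean(cat0))

  # single replicate: dispersion 0 with a warning flag
  expect_warning(s1 <- summarize_by_category(e[e$library == "lib1", ]),
                 "single replicate")
  expect_true(all(s1$sd_fc == 0))
  expect_true(all(s1$n_libraries == 1))
})

test_that("category partition sums to 4^k within the enrichment table", {
  for (k in c(2, 3)) {
    nk <- 4^k
    kmers <- decode_kmer(0:(nk - 1), k)
    expect_equal(sum(table(at_category(kmers))), nk)
    expect_equal(length(unique(at_category(kmers))), k + 1)
  }
})
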