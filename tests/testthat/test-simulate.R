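# Simulator: affinity models, round retention, dataset layout,
# reproducibility, null behaviour.

test_that("affinity models map windows to (0, 1] as specified", {
  cons <- affinity_model("consensus", consensus = "TATTA", lambda = 0.1)
  seqs <- c(
    paste0("TATTA", strrep("G", 15)),  # exact: HD 0
    paste0("TATTG", strrep("G", 15)),  # best window HD 1
    strrep("G", 20)                    # HD 5 everywhere
  )
  aff <- selexkit:::affinity_max(seqs, cons)
  expect_equal(aff[1], 1)
  expect_equal(aff[2], 0.1)
  expect_equal(aff[3], 0.1^5, tolerance = 1e-12)

  at <- affinity_model("at_content", gamma = 2, window = 5)
  aff2 <- selexkit:::affinity_max(c(strrep("A", 20),
                                    paste0(strrep("G", 15), "ATATG"),
                                    strrep("C", 20)), at)
  expect_equal(aff2[1], 1)
  expect_equal(aff2[2], (4 / 5)^2)
  expect_equal(aff2[3], at$eps) # all-GC floored, still selectable

  expect_error(affinity_model("consensus"), "consensus")
  expect_error(affinity_model("consensus", consensus = "TATTA", lambda = 1.5))
  expect_error(affinity_model("at_content", gamma = 0))
})

test_that("cycle-0 pools are replicate-distinct, reproducible and uniform", {
  cfg <- sim_config(cycles = 0, reads_per_sample = 4000, n_replicates = 2,
                    seed = 71)
  pools <- simulate_cycle0(cfg)
  expect_equal(length(pools), 2)
  expect_true(all(nchar(pools[[1]]$seq) == 20))
  expect_false(identical(pools[[1]]$seq, pools[[2]]$seq)) # distinct sub-seeds
  pools2 <- simulate_cycle0(cfg)
  expect_identical(pools, pools2)

  pm <- positional_model(tibble::tibble(id = pools[[1]]$id,
                                        seq = pools[[1]]$seq, qual = NA))
  sigma <- sqrt(0.25 * 0.75 / 4000)
  expect_true(all(abs(as.matrix(pm[c("A", "C", "G", "T")]) - 0.25) < 4 * sigma))
})

test_that("selection rounds enrich the consensus and cap retention at 1", {
  cfg <- sim_config(cycles = c(0, 1, 2), reads_per_sample = 20000,
                    n_replicates = 1, selection_strength = 1,
                    background_capture = 0.01,
                    affinity = affinity_model("consensus", consensus = "TATTA",
                                              lambda = 0.1),
                    seed = 72)
  pool <- simulate_cycle0(cfg)[[1]]
  has_motif <- function(p) mean(grepl("TATTA", p$seq, fixed = TRUE))
  f0 <- has_motif(pool)
  r1 <- select_round(pool, cfg, seed = 100)
  f1 <- has_motif(r1)
  r2 <- select_round(r1, cfg, seed = 101)
  f2 <- has_motif(r2)
  expect_equal(nrow(r1), nrow(pool)) # amplified back to size
  expect_gt(f1, f0)
  expect_gt(f2, f1)

  # extreme parameters: retention probability capped at 1, no error
  cfg_hot <- sim_config(cycles = 0:1, reads_per_sample = 100,
                        selection_strength = 1, background_capture = 1,
                        n_replicates = 1, seed = 73)
  r <- select_round(simulate_cycle0(cfg_hot)[[1]], cfg_hot, seed = 1)
  expect_equal(nrow(r), 100)
})

test_that("null selection (s = 0) leaves k-mer fractions within sampling noise", {
  cfg <- sim_config(cycles = 0:1, reads_per_sample = 10000, n_replicates = 1,
                    selection_strength = 0, background_capture = 0.5,
                    seed = 74)
  pool <- simulate_cycle0(cfg)[[1]]
  sel <- select_round(pool, cfg, seed = 200)
  f_in <- kmer_fractions(count_kmers(tibble::tibble(id = pool$id, seq = pool$seq,
                                                    qual = NA), 5))$fraction
  f_out <- kmer_fractions(count_kmers(tibble::tibble(id = sel$id, seq = sel$seq,
                                                     qual = NA), 5))$fraction
  lfc <- log2((f_out + 1e-3) / (f_in + 1e-3))
  expect_lt(max(abs(lfc)), 1) # no 5-mer shifts by as much as 2-fold
  expect_lt(mean(abs(lfc)), 0.2)
})

test_that("the default 3-replicate cycles 0/1/3/6 design lays out 21 samples", {
  cfg <- sim_config(reads_per_sample = 50, seed = 75)
  sim <- simulate_selex(cfg)
  expect_equal(length(sim$samples), 21)
  m <- sim$meta
  expect_equal(nrow(m), 21)
  expect_equal(sum(m$cycle == 0), 3)
  expect_equal(sum(!m$is_control), 9)  # protein arm at cycles 1/3/6 x 3 reps
  expect_equal(sum(m$is_control), 12)  # 3 cycle-0 + 9 no-protein controls
  expect_equal(unique(table(m$library)), 7L)
  # cycle-0-only config
  cfg0 <- sim_config(cycles = 0, reads_per_sample = 10, n_replicates = 3,
                     seed = 76)
  expect_equal(nrow(simulate_selex(cfg0)$meta), 3)
})

test_that("simulate_dataset writes reproducible files parseable end to end", {
  cfg <- sim_config(cycles = c(0, 1), reads_per_sample = 300, n_replicates = 2,
                    sequencing_error_rate = 0.002, seed = 77)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  res1 <- simulate_dataset(cfg, d1, gzip = FALSE)
  res2 <- simulate_dataset(cfg, d2, gzip = FALSE)
  expect_equal(nrow(res1$files), 6) # 2 reps x (cycle0 + protein + control)
  for (i in seq_len(nrow(res1$files))) { # byte-identical under the same seed
    expect_identical(readLines(res1$files$file[i]), readLines(res2$files$file[i]))
  }
  meta <- read_sample_sheet(file.path(d1, "metadata.tsv"))
  expect_equal(meta$sample_name, res1$files$sample_name)

  reads <- read_seqs(res1$files$file[1])
  expect_true(all(nchar(reads$seq) == cfg$read_length))
  expect_true(all(phred_scores(reads$qual[1])[[1]] == 40))
  # the i7 index rides in the header and demultiplexes back to the sample
  tagged <- illumina_index(reads)
  expect_equal(unique(tagged$barcode), seqlib_barcodes()$barcode[1])
  man <- yaml::read_yaml(res1$manifest)
  expect_equal(man$seed, 77)
  expect_equal(man$config$reads_per_sample, 300)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("insert recovery: trimming a simulated sample returns 20 bp inserts", {
  cfg <- sim_config(cycles = 0, reads_per_sample = 500, n_replicates = 1,
                    sequencing_error_rate = 0, seed = 78)
  d <- tempfile()
  res <- simulate_dataset(cfg, d, gzip = TRUE)
  trimmed <- trim_reads(read_seqs(res$files$file[1]))
  expect_equal(trim_summary(trimmed)$passed, 500)
  expect_true(all(nchar(trimmed$seq) == 20))
  # with no sequencing error the trimmed reads are exactly the inserts
  sim <- simulate_selex(cfg)
  expect_equal(trimmed$seq, sim$samples[[1]]$seq)
  unlink(d, recursive = TRUE)
})
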