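# Seeded generator of multi-cycle HT-SELEX datasets. Each replicate
# library starts as an independent pool of uniform random inserts; a
# selection round retains each molecule with probability
#   p = b + (1 - b) * s * max_w affinity(w)
# (b = wash-resistant background capture, s = selection strength, the
# max over k-windows modelling single-site occupancy), then re-amplifies
# by uniform resampling with replacement back to the pool size. The
# no-protein control arm runs the same rounds with s = 0, so it carries
# exactly the background/PCR bias the real control is meant to measure.

#' Affinity models for simulated selection
#'
#' Two functional forms, both mapping a DNA window to an affinity in
#' `(0, 1]`:
#'
#' * `consensus`: `affinity = lambda^HammingDistance(window, consensus)` —
#'   a single preferred motif with geometrically penalised mismatches
#'   (a specific binder).
#' * `at_content`: `affinity = (n_AT(window) / window_length)^gamma` — a
#'   promiscuous binder preferring AT-rich sequence of any arrangement.
#'
#' An affinity floor `eps` keeps all-GC windows selectable at a
#' machine-positive probability.
#'
#' @param kind `"consensus"` or `"at_content"`.
#' @param consensus Consensus motif (required for `kind = "consensus"`).
#' @param lambda Per-mismatch affinity factor in (0, 1); default 0.1.
#' @param gamma Exponent on the A/T fraction (> 0); default 1.
#' @param window Window length for `at_content` (default 5).
#' @param eps Affinity floor (default 1e-6).
#' @return A list of class `affinity_model`.
#' @export
affinity_model <- function(kind = c("consensus", "at_content"),
                           consensus = NULL, lambda = 0.1, gamma = 1,
                           window = 5L, eps = 1e-6) {
  kind <- match.arg(kind)
  if (kind == "consensus") {
    if (is.null(consensus)) abort("consensus motif required for kind = \"consensus\"")
    consensus <- toupper(consensus)
    check_dna(consensus, allow_n = FALSE, what = "consensus")
    if (!(lambda > 0 && lambda < 1)) abort("lambda must be in (0, 1)")
    window <- nchar(consensus)
  } else {
    window <- as.integer(window)
    if (gamma <= 0) abort("gamma must be positive")
    if (window < 1L) abort("window must be >= 1")
  }
  structure(list(kind = kind, consensus = consensus, lambda = lambda,
                 gamma = gamma, window = window, eps = eps),
            class = "affinity_model")
}

# Max-over-windows affinity for each sequence (uniform length assumed).
affinity_max <- function(seqs, model) {
  n <- length(seqs)
  if (n == 0) return(numeric())
  L <- nchar(seqs[1])
  k <- model$window
  if (L < k) return(rep(model$eps, n))
  if (model$kind == "consensus") {
    cons <- strsplit(model$consensus, "")[[1]]
    minhd <- rep(k, n)
    for (i in seq_len(L - k + 1L)) {
      hd <- integer(n)
      for (j in seq_len(k)) {
        hd <- hd + (substr(seqs, i + j - 1L, i + j - 1L) != cons[j])
      }
      minhd <- pmin(minhd, hd)
    }
    aff <- model$lambda^minhd
  } else {
    is_at <- lapply(seq_len(L), function(i) substr(seqs, i, i) %in% c("A", "T"))
    maxat <- integer(n)
    ws <- Reduce(`+`, is_at[seq_len(k)])
    maxat <- ws
    if (L > k) {
      for (i in seq(k + 1L, L)) {
        ws <- ws + is_at[[i]] - is_at[[i - k]]
        maxat <- pmax(maxat, ws)
      }
    }
    aff <- (maxat / k)^model$gamma
  }
  pmax(aff, model$eps)
}

#' Simulation configuration
#'
#' Full parameterisation of a multi-cycle HT-SELEX simulation. The
#' defaults mirror the worked experimental design: a 20 bp random insert,
#' three independent replicate libraries, samples sequenced at cycles
#' 0/1/3/6, 20,000 reads per sample (a depth in the range recommended
#' for HT-SELEX quantification), a promiscuous AT-content binder, and a
#' no-protein control arm per replicate.
#'
#' @param insert_length Random insert length in bp (default 20).
#' @param cycles Sorted set of cycles to emit samples for (0 = the
#'   unselected library; default `c(0, 1, 3, 6)`).
#' @param reads_per_sample Reads per emitted sample (default 20000).
#' @param n_replicates Independent replicate libraries (default 3).
#' @param selection_strength `s` in `[0, 1]`: weight of affinity-driven
#'   retention (default 0.85).
#' @param background_capture `b` in `[0, 1]`: affinity-blind retention
#'   probability — the wash-resistant background the no-protein control
#'   measures (default 0.1).
#' @param affinity An [affinity_model()].
#' @param sequencing_error_rate Per-base substitution rate applied when
#'   reads are written (default 0.001, i.e. ~Q30 calls).
#' @param read_length Single-end read length in nt for
#'   [simulate_dataset()] (default 51; single-end reads comfortably
#'   cover the 20 bp insert).
#' @param protein Label for the protein arm (default `"ZFC4"`).
#' @param barcodes A [barcode_table()]; defaults to the 21 built-in i7
#'   barcodes ([seqlib_barcodes()]).
#' @param seed Master seed; every stochastic step derives its own
#'   sub-stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(insert_length = 20L,
                       cycles = c(0L, 1L, 3L, 6L),
                       reads_per_sample = 20000L,
                       n_replicates = 3L,
                       selection_strength = 0.85,
                       background_capture = 0.1,
                       affinity = affinity_model("at_content"),
                       sequencing_error_rate = 0.001,
                       read_length = 51L,
                       protein = "ZFC4",
                       barcodes = NULL,
                       seed = 1L) {
  insert_length <- as.integer(insert_length)
  cycles <- sort(unique(as.integer(cycles)))
  reads_per_sample <- as.integer(reads_per_sample)
  n_replicates <- as.integer(n_replicates)
  if (insert_length < 1L) abort("insert_length must be positive")
  if (any(cycles < 0L)) abort("cycles must be >= 0")
  if (reads_per_sample < 1L) abort("reads_per_sample must be positive")
  if (n_replicates < 1L) abort("n_replicates must be >= 1")
  if (selection_strength < 0 || selection_strength > 1) {
    abort("selection_strength must be in [0, 1]")
  }
  if (background_capture < 0 || background_capture > 1) {
    abort("background_capture must be in [0, 1]")
  }
  if (sequencing_error_rate < 0 || sequencing_error_rate >= 1) {
    abort("sequencing_error_rate must be in [0, 1)")
  }
  stopifnot(inherits(affinity, "affinity_model"))
  if (read_length < insert_length) {
    abort("read_length must cover the insert")
  }
  structure(list(insert_length = insert_length, cycles = cycles,
                 reads_per_sample = reads_per_sample,
                 n_replicates = n_replicates,
                 selection_strength = selection_strength,
                 background_capture = background_capture,
                 affinity = affinity,
                 sequencing_error_rate = sequencing_error_rate,
                 read_length = as.integer(read_length),
                 protein = protein, barcodes = barcodes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_inserts <- function(n, L) {
  m <- matrix(sample(DNA_BASES, n * L, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
}

#' Draw the unselected cycle-0 pools
#'
#' One pool of `reads_per_sample` uniform random inserts per replicate,
#' each replicate on its own derived seed — emulating independently
#' synthesised libraries with slightly different sequence distributions.
#'
#' @param cfg A [sim_config()].
#' @return A list of read tibbles (columns `id`, `seq`), one per
#'   replicate.
#' @export
simulate_cycle0 <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed, cfg$n_replicates)
  lapply(seq_len(cfg$n_replicates), function(r) {
    seq <- with_seed(seeds[r],
                     random_inserts(cfg$reads_per_sample, cfg$insert_length))
    tibble(id = sprintf("lib%d:%d", r, seq_along(seq)), seq = seq)
  })
}

#' One SELEX round: bind, wash, amplify
#'
#' Retains each molecule independently with
#' `p = b + (1 - b) * s * max_w affinity(w)` (capped at 1) and then
#' resamples the retained molecules with replacement back to the input
#' pool size, modelling unbiased PCR re-amplification.
#'
#' @param pool Read tibble of inserts.
#' @param cfg A [sim_config()].
#' @param seed Seed for this round (default: derived from `cfg$seed`).
#' @return A read tibble of the same size as `pool`.
#' @export
select_round <- function(pool, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(pool) == 0) abort("pool is empty")
  with_seed(seed, {
    aff <- affinity_max(pool$seq, cfg$affinity)
    p <- pmin(1, cfg$background_capture +
                (1 - cfg$background_capture) * cfg$selection_strength * aff)
    keep <- which(runif(nrow(pool)) < p)
    if (!length(keep)) {
      abort(paste0("no molecules retained in this round; ",
                   "use a background_capture > 0 so washing never empties the pool"),
            class = "selexkit_sim_error")
    }
    idx <- keep[sample.int(length(keep), nrow(pool), replace = TRUE)]
    tibble(id = sprintf("%s:a%d", pool$id[idx], seq_len(nrow(pool))),
           seq = pool$seq[idx])
  })
}

#' Simulate a full multi-cycle HT-SELEX experiment in memory
#'
#' Runs, per replicate library, a protein-selection lineage and a
#' no-protein control lineage (`s = 0`) from the same cycle-0 pool,
#' snapshotting every cycle listed in `cfg$cycles`. Cycle-0 snapshots are
#' emitted once per replicate with protein `"None"`, matching the usual
#' sample layout (e.g. 3 replicates at cycles 0/1/3/6 give 21 samples).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `selex_sim` with elements `samples` (named
#'   list of insert read tibbles), `meta` (tibble compatible with
#'   [read_sample_sheet()] output) and `config`.
#' @export
simulate_selex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  maxc <- max(cfg$cycles)
  pools0 <- simulate_cycle0(cfg)
  round_seeds <- if (maxc > 0) {
    matrix(derive_seeds(cfg$seed + 1L, cfg$n_replicates * maxc * 2L),
           nrow = cfg$n_replicates)
  }
  cfg_null <- cfg
  cfg_null$selection_strength <- 0
  snap <- list() # keyed snap[[cycle]][[arm]][[rep]]
  for (r in seq_len(cfg$n_replicates)) {
    pro <- pools0[[r]]
    ctl <- pools0[[r]]
    if (0L %in% cfg$cycles) snap[["0"]][["cycle0"]][[r]] <- pools0[[r]]
    if (maxc > 0) for (cy in seq_len(maxc)) {
      pro <- select_round(pro, cfg, seed = round_seeds[r, 2L * cy - 1L])
      ctl <- select_round(ctl, cfg_null, seed = round_seeds[r, 2L * cy])
      if (cy %in% cfg$cycles) {
        snap[[as.character(cy)]][["protein"]][[r]] <- pro
        snap[[as.character(cy)]][["control"]][[r]] <- ctl
      }
    }
  }
  samples <- list()
  meta_rows <- list()
  for (cy in as.character(sort(cfg$cycles))) {
    for (arm in c("cycle0", "protein", "control")) {
      if (is.null(snap[[cy]][[arm]])) next
      for (r in seq_along(snap[[cy]][[arm]])) {
        nm <- sprintf("S%02d", length(samples) + 1L)
        samples[[nm]] <- snap[[cy]][[arm]][[r]]
        meta_rows[[nm]] <- tibble(
          sample_name = nm,
          library = sprintf("lib%d", r),
          protein = if (arm == "protein") cfg$protein else "None",
          cycle = as.integer(cy),
          is_control = arm != "protein"
        )
      }
    }
  }
  meta <- bind_rows(meta_rows)
  structure(list(samples = samples, meta = meta, config = cfg),
            class = "selex_sim")
}

#' @export
print.selex_sim <- function(x, ...) {
  cat(sprintf("<selex_sim> %d samples (%d replicates, cycles %s), %d reads/sample\n",
              length(x$samples), x$config$n_replicates,
              paste(x$config$cycles, collapse = "/"),
              x$config$reads_per_sample))
  invisible(x)
}

apply_sequencing_error <- function(seqs, rate, seed) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  with_seed(seed, {
    n <- length(seqs)
    L <- nchar(seqs[1])
    hit <- which(runif(n * L) < rate)
    if (length(hit)) {
      rid <- (hit - 1L) %% n + 1L
      pos <- (hit - 1L) %/% n + 1L
      mat <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
      orig <- mat[cbind(rid, pos)]
      alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                      "A", "C", "T",  "A", "C", "G"), nrow = 3)
      mat[cbind(rid, pos)] <- alt[cbind(sample.int(3L, length(hit), replace = TRUE),
                                        match(orig, DNA_BASES))]
      seqs <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
    }
    seqs
  })
}

#' Simulate an HT-SELEX dataset on disk
#'
#' Runs [simulate_selex()] and materialises it the way a sequencing run
#' would: each sample's inserts are embedded in the sequencing construct
#' (the read continues from the insert into the constant 3' region, the
#' reverse-complemented i7 barcode and P7 flank), truncated to the read
#' length, subjected to per-base sequencing error, given constant
#' quality 40, and written as FASTQ with Illumina-style headers carrying
#' the sample index. A metadata sheet (parseable by
#' [read_sample_sheet()]) and a YAML manifest recording the seed and all
#' parameters are written alongside.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files (default `TRUE`).
#' @return Invisibly, a list with `files` (tibble: `sample_name`,
#'   `file`, `n_reads`), `meta`, and the manifest path.
#' @export
simulate_dataset <- function(cfg, out_dir, gzip = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_selex(cfg)
  bt <- cfg$barcodes %||% seqlib_barcodes()
  n_samp <- length(sim$samples)
  if (nrow(bt) < n_samp) {
    abort(sprintf("design needs %d barcodes but the barcode table has %d",
                  n_samp, nrow(bt)),
          class = "selexkit_barcode_error")
  }
  # Samples take the names of the barcodes they are tagged with.
  old_names <- names(sim$samples)
  names(sim$samples) <- bt$sample_name[seq_len(n_samp)]
  sim$meta$sample_name <- bt$sample_name[match(sim$meta$sample_name, old_names)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  err_seeds <- derive_seeds(cfg$seed + 2L, n_samp)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  files <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    nm <- names(sim$samples)[i]
    bc <- bt$barcode[i]
    inserts <- sim$samples[[i]]
    full <- paste0(inserts$seq, post_insert_readthrough(bc))
    full <- substr(full, 1L, cfg$read_length)
    full <- apply_sequencing_error(full, cfg$sequencing_error_rate, err_seeds[i])
    reads <- tibble(
      id = sprintf("%s:%d 1:N:0:%s", nm, seq_len(nrow(inserts)), bc),
      seq = full,
      qual = strrep(intToUtf8(40L + 33L), nchar(full))
    )
    f <- file.path(out_dir, paste0(nm, ext))
    write_seqs(reads, f, format = "fastq")
    files[[i]] <- tibble(sample_name = nm, file = f, n_reads = nrow(reads))
  }
  files <- bind_rows(files)
  meta_path <- file.path(out_dir, "metadata.tsv")
  write_sample_sheet(sim$meta, meta_path)
  manifest <- list(
    tool = "selexkit", version = as.character(utils::packageVersion("selexkit")),
    seed = cfg$seed,
    retention_model = "p = b + (1 - b) * s * max_window_affinity",
    config = list(
      insert_length = cfg$insert_length, cycles = cfg$cycles,
      reads_per_sample = cfg$reads_per_sample,
      n_replicates = cfg$n_replicates,
      selection_strength = cfg$selection_strength,
      background_capture = cfg$background_capture,
      affinity = cfg$affinity[!vapply(cfg$affinity, is.null, logical(1))],
      sequencing_error_rate = cfg$sequencing_error_rate,
      read_length = cfg$read_length, protein = cfg$protein
    ),
    samples = stats::setNames(as.list(files$n_reads), files$sample_name)
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(files = files, meta = sim$meta, manifest = manifest_path))
}
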