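---
title: "Methods: k-mer enrichment analysis of HT-SELEX libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer enrichment analysis of HT-SELEX libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexkit)
```

# The experiment this package models

HT-SELEX reads out the DNA-binding preference of a protein by iterated
in-vitro selection. A single-stranded 63 nt template — a 21 nt constant
5' flank, a 20 base random insert, a 22 nt constant 3' flank — is
converted by PCR with two flanking primers into an 83 bp double-stranded
"cycle 0" library in which, ideally, every 20-mer is represented. Each
selection cycle incubates the library with the affinity-tagged protein,
captures complexes on beads, washes, and re-amplifies the retained DNA.
After the desired number of cycles, each sample is amplified once more
with sequencing primers that add Illumina adapters and a sample-specific
8 bp i7 barcode, giving a 144 bp construct; pooled samples are sequenced
single-end, which is sufficient because the insert sits immediately
downstream of the read-1 priming site.

Three independently synthesised libraries serve as technical replicates
(each synthesis has a slightly different sequence distribution), and
every cycle carries a no-protein control that measures wash and PCR
biases. Analysis is deliberately simple and exhaustive: count every
k-mer in every sample, normalise to cycle 0, and look at the result —
there is no motif discovery step that could miss promiscuous binding
spread over hundreds of related words.

# The quantities computed

**Presence fraction.** For k-mer $w$ in a sample of $n$ reads,
$f(w) = \frac{\#\{\text{reads containing } w\}}{n}$. We use per-read
presence rather than raw occurrence frequency because it is bounded in
$[0,1]$, robust to repeats within one read, and standard for HT-SELEX
k-mer work. Occurrence counts are retained in the same table, so either
statistic can be derived. Windows containing `N` are skipped and
excluded from the window total.

**Fold change.** With presence counts $p_s$, $p_0$ and read totals
$n_s$, $n_0$ for a selected sample and its cycle-0 reference,
$$\mathrm{FC}(w) = \frac{(p_s(w)+\alpha)/(n_s+\alpha)}
                        {(p_0(w)+\alpha)/(n_0+\alpha)},$$
with pseudocount $\alpha = 1$ by default. The pseudocount makes fold
changes finite and symmetric for k-mers absent from either sample; a
sample compared against itself gives exactly 1 for every k-mer. The
default pairing is *matched library*: each sample is normalised to the
cycle-0 sample of its own replicate library, precisely because the
replicate libraries are known to start from different distributions. A
pooled-cycle-0 pairing is available for designs without matched
references.

**A/T categories.** Each k-mer is labelled with its number of A/T
letters (0 to $k$; at $k=5$, six categories of
$\binom{5}{j} \cdot 32$ k-mers). The category summary first averages
fold changes over k-mers within each replicate library, then averages
those means across libraries; the reported dispersion is the standard
deviation across replicate libraries (the data are balanced — every
library sees every k-mer — so the two orders of averaging coincide; we
report SD rather than SEM as the more conservative bar). Controls are
summarised side by side and never subtracted: the control answers "is
the background flat?", not "what should I subtract?".

**Depth concordance.** To ask how much sequencing a sample needs, the
reads are sub-sampled without replacement at a series of depths (one
shared sub-sample per depth), presence fractions are recomputed for
each k, and the squared Spearman rank correlation against the
full-depth fractions is reported per (depth, k). Squaring follows the
convention of the corresponding diagnostic plot; the signed coefficient
is available (`squared = FALSE`). Fractions rather than raw counts are
correlated — within a comparison the read count is fixed, so the ranks
are identical either way. When the sub-sample equals the full pool the
vectors are identical and the report contains exactly 1.0, bypassing
floating-point noise in the rank computation.

# Numerical and design choices

**Primer annealing with wildcard templates.** In-silico PCR locates the
longest 3'-terminal suffix of each primer that matches the template
(reverse-complemented for the reverse primer). The design template
contains a 20 base `N` run, and a literal "longest suffix, N matches
anything" rule would let a primer suffix "anneal" almost entirely on
top of the random insert — two paired bases plus twenty wildcards —
shortening the predicted product. We therefore rank candidate sites by
the number of *exactly paired* (non-N) bases, require at least
`min_anneal` (default 15) of them, and break ties towards longer
suffixes, then leftmost position. Under this rule the printed template
and primers reproduce the expected 83 bp and 144 bp products exactly,
and re-amplifying a product with the same primers is a fixed point.
Equally good sites at disjoint positions raise an ambiguity error
rather than silently picking one. Coordinates are 0-based half-open
internally; no mismatch tolerance or thermodynamics is modelled, since
the design primers match their targets exactly.

**Trimming.** The quality trim is fixed to *tail* mode — remove the
maximal 3' run of bases below the threshold (default Phred 30) — the
simplest semantics consistent with the insert sitting at the 5' end of
the read; only 3' trimming is safe there. The hard trim then keeps the
5'-most 20 bases. Reads are never renamed; original ids are preserved.
An optional exact-match 5' prefix clip handles runs whose reads start
upstream of the insert, since instrument configurations differ on this.
Qualities are fixed to Phred+33, the encoding of all current Illumina
instruments.

**K-mer engine.** K-mers are encoded as base-4 integers (A=0 ... T=3,
leftmost base most significant) and tallied with vectorised window
scans; an independent plain-substring oracle pins the semantics in the
test suite. `k` is capped at 10: the exhaustive $4^k$ table at
$k = 11$ (4.2M entries per sample) is beyond the intended scale, and
the cap is surfaced as an explicit capability error. By default the
read strand is counted as sequenced; `canonical = TRUE` collapses each
window onto the numerically smaller of itself and its reverse
complement (SELEX ligands are duplexes, but strand-collapsing is left
opt-in rather than silently changing the statistic). Ranking ties are
broken by ascending code — equivalently alphabetically — so top-k-mer
lists are deterministic.

**Barcodes and demultiplexing.** The 21 built-in i7 barcodes (extracted
from the reverse sequencing primers between the P7 flank and the
constant annealing region) are 8 bp, unique, and at least 2 mismatches
apart — the constraints any extension of the set must keep, which
`validate_barcode_set()` checks, reporting per-position base
composition without thresholding it. Because the guaranteed minimum
distance is 2, a one-mismatch assignment cannot be proven unambiguous,
so `demultiplex()` defaults to exact matching and leaves anything
matching zero or two-plus barcodes unassigned; the partition is always
exhaustive and disjoint. Barcodes are stored exactly as printed in the
primers; whether an instrument reports the i7 index as-is or
reverse-complemented varies by workflow, so the observed index is
supplied either as a header tag or as a read suffix, per run.

# The simulator: what it emulates, and what it does not

The generator exists so that selection, normalisation, controls and
depth analysis can be tested end to end without sequencing data. Its
defaults are the modelled study design: 20 bp inserts, 3 replicate
libraries, samples at cycles 0/1/3/6, 20,000 reads per sample (within
the 10,000–50,000 per sample recommended for HT-SELEX quantification),
and a promiscuous AT-content binder with a no-protein control arm.

Selection is operational, not thermodynamic. Each molecule is retained
with probability $p = b + (1-b)\, s \cdot \max_w a(w)$: $b$ is the
affinity-blind, wash-resistant background the control arm measures
(default 0.1), $s \in [0,1]$ scales selection strength (default 0.85),
and the max over windows models single-site occupancy. Two affinity
forms are provided: $a = \lambda^{\mathrm{HD}(w,\,\text{consensus})}$
for a specific binder (default $\lambda = 0.1$) and
$a = (n_{AT}(w)/k)^{\gamma}$ for a promiscuous AT-rich binder (default
$\gamma = 1$), with a floor of $10^{-6}$ so all-G/C windows remain
selectable. PCR is uniform resampling with replacement back to pool
size — deliberately bias-free, because detecting amplification bias
empirically is exactly what the negative control is for. Sequencing
error is uniform per-base substitution (default 0.001, ~Q30);
simulated FASTQ carries constant quality 40, so quality trimming is
exercised with dedicated low-quality fixtures rather than the
simulator. Every stochastic step draws its own stream seed derived
from the master seed, making outputs byte-identical across runs.

Real data differ in ways the simulator does not attempt: synthesis
bias in the "random" insert, PCR heteroduplexes ("bubble products"),
position- and quality-dependent error profiles, protein concentration
and competition effects, and carry-over between cycles. Passing the
simulated suites therefore demonstrates that the *computation* is
correct and well calibrated (a null selection yields fold changes at 1
within sampling noise; a planted motif is recovered; AT-content
selection produces category-monotone enrichment with flat controls),
not that any particular biological claim holds for a new dataset.

# Problem sizes and runtime

The test suite exercises the pipeline at deliberately reduced scale:
planted-motif recovery uses 3 replicates x 50,000 reads over cycles
0–2; null calibration uses 10,000 reads; the A/T signature uses
3 x 20,000 reads over cycles 0–3; depth concordance sub-samples a
100,000-read enriched sample at 1k/10k/50k for k = 5–10. These sizes
keep the full suite around a minute on one CPU while leaving each
qualitative signature far from its decision boundary. Real analyses
at e.g. 3M reads per sample run through the same code paths — the
engine is vectorised and the 4^k tables, not the read counts, are the
limiting factor.

# Known limitations

* No probabilistic motif models (PWMs, HMMs) or gapped k-mers; the
  package stops at exhaustive contiguous k-mer statistics.
* No statistical significance testing of enrichment; the replicate
  dispersion and the negative control are the calibration instruments.
* Paired-end reads and SAM/BAM inputs are out of scope (the assay is
  single-end by design).
* `k > 10` is refused rather than streamed.
* The in-silico PCR models exact annealing only — no melting
  temperature, mispriming or heteroduplex prediction; those remain
  wet-lab QC concerns.
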