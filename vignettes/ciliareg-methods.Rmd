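---
title: "Methods: models, statistics and synthetic data in ciliareg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and synthetic data in ciliareg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliareg)
```

## The scientific problem

Sensory cilia in *C. elegans* are built by a battery of effector genes
(IFT particles, BBSome components, kinesins, dyneins, ciliary channels and
receptors) expressed in the 60 ciliated sensory neurons. The master
regulator of this battery is the RFX transcription factor DAF-19, which
binds a long, imperfectly palindromic promoter motif — the X-box. Residual
battery expression in *daf-19* nulls implies at least one co-regulator;
candidate co-regulators can be found computationally by combining
(i) motif analysis of battery promoters, (ii) single-cell expression
enrichment in ciliated neurons, (iii) TF ChIP-seq binding to battery
genes, and then validated genetically by testing whether the double loss
of the two factors is worse than the product of the single losses — the
multiplicative (epistasis) model.

`ciliareg` implements each of these steps as a reusable, tested component,
together with a synthetic-data generator that emulates all the inputs with
known ground truth, so the full pipeline is exercisable and falsifiable
without any external download.

## The gene battery

A `GeneBattery` is a set of unique gene ids partitioned into four
categories — `core` (all cilia), `subtype` (neuron-type-specific ciliary
function), `broad` (ciliated-system expression without a defined core
role) and `male`. The partition is an invariant: `category_counts()`
always sums to the battery size. Loaders normalize the decorated category
labels found in curated tables (quotes, asterisks, case, "Sub-type"
variants) and collapse duplicate ids only when their categories agree;
conflicting duplicates are an error, because silently keeping one would
corrupt every per-category rate downstream. When a table carries only
display names, the public name serves as the identifier — curated lists
mix locus and public names, and forcing a single id column would reject
real inputs.

## Coordinates

Everything internal is 0-based, half-open, matching BED/narrowPeak
arithmetic. GFF3 input (1-based, closed) is converted on read. A gene
model carries a TSS and a translational start (TLS); promoters default to
the 700 bp immediately upstream of the TLS, the convention used when the
battery's regulatory sequences were assembled, and the TSS anchors the
annotation window.

## Motif scanning

`build_pwm()` turns a count matrix into per-position log2-odds against a
background composition. The default pseudocount 0.01 (scaled by the
background) keeps every cell finite; an explicit zero-pseudocount mode
scores impossible bases as −1e9 rather than −Inf so window sums stay
representable. `scan_pwm()` scores every window on both strands (the
reverse strand via the reverse-complemented matrix, so coordinates stay
forward) and reports windows at or above the threshold. The default
threshold is 0.8 × the maximum attainable score: the fraction-of-max form
is scale-free, and no absolute threshold is canonical for X-box calling.
Windows containing `N` never match, at any threshold. The scanner is
tested against an exhaustive per-window oracle on short sequences and
against the strand-symmetry identity (scanning a reverse complement gives
the mirrored match set).

`kmer_enrichment()` is a deliberate stand-in for classical promoter
oligo-analysis: it pools k-length windows over both strands under
canonical k-mers (a word and its reverse complement are one species;
palindromes count once per window), computes each canonical k-mer's
expected frequency under an order-0 background (estimated from the input
by default), and takes a binomial upper tail with Benjamini–Hochberg
control across all canonical k-mers. Overlapping windows make the
binomial an approximation; on null sequences the realized FDR sits well
below the nominal level in our simulations. Markov backgrounds above
order 0 and motif assembly from significant words are out of scope.

## Peak annotation and TF prioritization

`annotate_peaks()` reduces each peak to a point anchor — the summit when
called, else the midpoint — and assigns exactly one feature by precedence:
`promoter` if the anchor lies in a gene's strand-aware
`[TSS − 2000, TSS + 1000)` window (the window used throughout this
pipeline), else `genic`, else `downstream` (within 3 kb past a gene end in
transcript orientation), else `intergenic`. The assigned gene is the one
whose window contains the anchor (nearest TSS if several), otherwise the
nearest TSS; exact ties break to the lexicographically smaller gene id so
annotation is order-invariant and reproducible. A point anchor, rather
than full-interval overlap, makes the distance and tie semantics exact and
testable; the 4-class hierarchy is intentionally simpler than the 7-class
scheme of full annotation suites, because only the promoter fraction and
the gene assignment feed the analyses here.

`battery_binding()` counts a battery gene as bound when at least one peak
is assigned to it, with per-category fractions over each category's size;
a `features =` filter restricts which assignments count.
`prioritize_tfs()` regresses battery genes bound on total peaks across a
TF compendium (OLS), computes externally studentized residuals, and flags
TFs beyond the two-sided t critical value at a Bonferroni-adjusted 0.05 —
a dedicated co-regulator binds far more battery genes than its peak count
predicts. The outlier criterion is ours (none is canonical); Bonferroni
keeps the family-wise false-flag rate at the stated level, which the null
simulation confirms.

## Central enrichment and positional statistics

`peak_windows()` extracts fixed-length sequences (±210 bp around each
peak center, giving the 420 bp consensus length) and excludes, rather than
clips, windows overhanging a chromosome edge — unequal windows would break
the positional null. `central_enrichment()` takes the single best-scoring
site per window over both strands ("best site" mode keeps the binomial
null exact), calls the window matched if that score reaches the
threshold, and for each candidate central width w tests the count of
best-site centers within w/2 of the window center against
Binomial(n, p_w), p_w the exact fraction of possible offsets whose site
center falls in the band. The minimum p over the width grid
{20, 40, …, 200} is Bonferroni-multiplied by the number of widths: a fixed
grid keeps the correction explicit, at the cost of conservatism (the
null rejection rate sits below nominal, which the 200-replicate
uniform-position simulation verifies as superuniformity).

`xbox_peak_distance()` measures each X-box midpoint to the nearest peak
*center* (not edge) on its chromosome. X-boxes on peak-free chromosomes
receive +Inf; by default they count in the denominator as "not within",
and `drop_peakless_chroms = TRUE` provides the other denominator, since
either convention is defensible. `classify_signatures()` is plain set
algebra over the battery into `xbox_and_peak` / `peak_only` / `xbox_only`
/ `neither`, with per-category breakdowns; ids outside the battery are
ignored with a message, never an error, because bound-gene lists span the
whole genome.

## Single-cell screen and correlation

Counts are normalized to counts-per-10k per cell before any mean or
correlation — correlation on raw counts conflates sequencing depth with
expression. The screen statistic is a one-sided Wilcoxon rank-sum on
per-cell normalized values (target class vs all other cells pooled),
chosen for robustness to the zero-inflated, overdispersed shape of
sc-RNA-seq counts; fold enrichment is the ratio of class means with the
other-class mean floored at a small epsilon (default 0.01 cp10k) so a
gene silent outside the target class gets a finite, large fold. A hit
requires fold ≥ 5 and BH-q ≤ 0.001, the classic screen thresholds. A
`max_class` mode compares against the maximum other class instead of the
pool (a stricter specificity screen); pooled is the default.
`class_detection_profile()` calls a gene detected in a class when it is
non-zero in ≥ 5% of that class's cells. `expression_correlation()` is
Pearson R on normalized values over a cell subset, with an `NA` sentinel
for zero-variance genes and per-set median/quartile summaries.

## Reporter statistics and the multiplicative model

Reporter comparisons mirror the spreadsheet workflow they replace: an F
pretest on the variances (α = 0.05) selects the pooled or Welch two-sample
t, Bonferroni-corrected over all pairs; regional comparisons use one-tailed
t (mutant < control) with BH step-up across regions at α = 0.05.

For synergy, per-animal counts become fold changes against the reference
genotype's mean, so the reference has mean fold change exactly 1. Under
the multiplicative null the combined mutant is expected at
E = m_a × m_b, the product of the two double-mutant mean fold changes.
The propagated error is the first-order product rule written as the sum
of relative errors, sd_E = E·(s_a/m_a + s_b/m_b); a quadrature mode
(√ of summed squared relative errors) and an SEM-based mode are available
because the convention is not universal. `synergy_test()` runs a
one-sample t of the combined mutant's per-animal fold changes against E
(two-sided by default, configurable), with verdicts `synergistic_loss`,
`consistent_with_multiplicative` or `greater_than_expected` at α = 0.05.

Two calibration facts matter and are worth stating plainly. First, with E
fixed at its true value the test holds its level: under the
multiplicative Poisson null at the default study conditions (reference
mean 60, multipliers 0.8 and 0.2, n = 10) the measured rejection rate is
≈ 0.05 over 500 replicates. Second, the plug-in procedure — E and the
reference mean estimated from the same experiment, E then treated as
fixed — is anti-conservative (we measure ≈ 0.19 at these settings),
because the uncertainty of E and the shared reference denominator are
ignored. That is a property of the procedure itself, not of this
implementation; the `conservative = TRUE` flag folds `sd_expected` into
the test denominator and (with SEM-based propagation) brings the realized
rate below nominal. Power against real synergy is high either way: at
interaction 0.2 and n = 10 the loss verdict fires in essentially every
replicate.

`rescue_test()` is the two-sided Fisher exact test on 2×2 on/off tables,
verified against full hypergeometric enumeration; the sample odds ratio
is reported with conventional 0/∞ handling. `behavior_index()` computes
the literal population index formulas (response, quadrant and half-plate
chemotaxis, sector and drop avoidance, dauer fraction), which respect
their stated bounds for any non-negative counts; Shapiro–Wilk normality
checking of replicate indexes delegates to `stats::shapiro.test`.

## The synthetic-data generator

The generator's defaults are the study conditions, chosen once:

* **Genome/genes** — 3 chromosomes × 1 Mb of i.i.d. sequence at GC 0.36
  (the *C. elegans* genome-wide value), 400 non-overlapping gene models
  (163 battery genes split 73/68/13/9 plus 237 background genes) spaced so
  that no TSS window overlaps a neighbouring gene's.
* **Motifs** — the X-box PWM default is a strong count matrix for the
  canonical RFX site GTTGCCATGGCAAC; the planted string is always the
  supplied PWM's maximum-likelihood consensus, forward or reverse
  complement at random, at a uniform offset within the 700 bp promoter.
  Planting probabilities 0.9/0.3/0.75/0.45 per category put X-boxes in
  ≈ 62% of battery genes, core-biased, as in the curated battery.
* **Peaks** — 21 TFs. The regulator binds each battery gene with
  probability 0.75 (core), 0.22 (subtype), 0.46 (broad/male) — the
  printed core/subtype binding rates, with broad/male set to land the
  overall rate near one gene in two — anchoring the peak on the planted
  X-box (jitter sd 50 bp emulating summit-call noise), and fills to 250
  peaks with background peaks rejection-sampled away from battery TSS
  windows so the truth table of bound genes is exact. Null TFs draw
  100–600 peaks, 40% of them centered on background-gene promoters and
  the rest uniform.
* **Single cell** — negative binomial counts (dispersion 0.5, typical
  sc-RNA-seq overdispersion) over three classes (300 ciliated, 400 other
  neuronal, 500 non-neuronal cells). The regulator's mean is ×8 in the
  target class; a 73-gene core set is coupled to it through a per-cell
  lognormal latent factor (sd 0.6, mean-normalized), and every other
  class carries its own program of equal mass so per-cell depth is
  balanced and normalization stays neutral. The planted fold of 8 sits
  deliberately above the fivefold pass threshold: an unbiased fold
  estimate of a regulator planted exactly at the threshold would clear it
  only half the time, which is a property of thresholding, not of the
  screen.
* **Reporter counts** — Poisson (or NB) around reference mean 60 with
  multipliers 0.8 and 0.2 for the two double mutants and
  triple = 0.8 × 0.2 × interaction; interaction 1 is the multiplicative
  null, 0.2 the strong-synergy condition used for power checks; n = 10
  animals per genotype.

Every generator takes the seed from the config (sub-seeded per generator)
and is byte-identical under a fixed seed; every recovery test compares
against the emitted truth table, never against re-derived values.

### What the synthetic world does and does not emulate

The synthetic genome is gene-dense relative to the real one (400 genes in
3 Mb, with the battery 41% of all genes instead of < 1%). Nearest-TSS
assignment therefore associates random peaks with battery genes far more
often than in real data, which has two consequences: recovery analyses
count a battery gene as bound through *promoter-assigned* peaks, and the
null TFs' promoter-biased peaks target the background gene pool, standing
in for the real genome's much larger non-ciliome complement (their
uniform component still hits battery windows at the genomic background
rate). Passing tests demonstrate that the statistics recover planted
truth under these conditions; they do not certify genome-scale behaviour
on real annotation builds, where feature proportions (e.g. the promoter
fraction) will differ. i.i.d. background sequence also lacks repeats and
compositional heterogeneity, so motif false-positive rates on real
genomes will be higher than here.

## Pipeline and problem sizes

`run_pipeline()` validates its config (unknown keys are errors), executes
the stages in dependency order, and writes a versioned JSON report
carrying the tool version, seed, resolved config and input checksums;
reruns under the same seed are byte-identical. The default problem sizes
(3 Mb genome, 21 TFs, 1200 cells, 500-replicate calibration loops) run
the full pipeline in well under a minute and the test suite in about
forty seconds on one CPU.

## Known limitations

* The central-enrichment p-value is Bonferroni-conservative over the
  width grid and ignores inter-window score correlation.
* The k-mer screen's binomial null ignores overlap dependence between
  windows of one sequence.
* The plug-in synergy test inherits the anti-conservatism discussed
  above; use `conservative = TRUE` with SEM propagation when a guaranteed
  level matters.
* Promoter extraction truncates at chromosome edges (with a warning)
  rather than padding; genes within 700 bp of an edge yield short
  promoters.
* No read-level simulation (FASTQ), no peak calling, no clustering or
  embedding of the single-cell matrix: inputs enter as peaks, counts and
  gene models.
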