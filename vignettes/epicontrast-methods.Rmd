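---
title: "Methods: comparative epigenomics of cultivar and nitrogen responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative epigenomics of cultivar and nitrogen responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicontrast)
library(dplyr)
```

## The analysis problem

Two crop cultivars with contrasting nitrogen-use strategies are profiled
across tissues under normal (NN) and low (LN) nitrogen: histone-mark peak
sets and signal from CUT&Tag-style assays, chromatin-state segmentations
over 200-bp bins, and matched transcriptomes. The questions the toolkit
answers are comparative: which peaks differ between cultivars or
conditions, how chromatin states redistribute, which distal (enhancer-like)
regions plausibly regulate which genes, whether dynamic regions are
enriched for QTL intervals, transcription-factor motifs or differentially
expressed genes, and how root phenotypes respond to low nitrogen.

`epicontrast` implements each of those stages as tibble-in/tibble-out
functions, plus a synthetic-data generator that plants known ground truth
so every stage can be validated quantitatively. All genomic coordinates
are 0-based half-open (BED native); GFF3 input is converted on read.

## Peak compartments

A peak is `promoter` if it overlaps the 3-kb window upstream of a TSS
(strand-aware, TSS base included), else `genic` if it overlaps a gene body
(TSS to TES), else `distal`; precedence is promoter > genic > distal. The
3000-bp default is the conventional promoter radius for these assays.
Because some annotation tools use symmetric windows, an option
`promoter_flank = "symmetric"` widens the window to ±3 kb; upstream-only
is the default. Ties at compartment boundaries are resolved by the
precedence order, and a peak on a chromosome with no annotated genes is
distal (with a message), not an error.

## Differential signal

For two sample groups the comparison is MA-based: with pseudocount
$c = 1$ signal unit (bounding $M$ at zero signal),

$$M = \log_2\frac{x_A + c}{x_B + c}, \qquad
  A = \tfrac12 \log_2\big((x_A + c)(x_B + c)\big).$$

Replicates are averaged per group for the $M$/$A$ display; a robust
least-absolute-deviations line of $M$ on $A$ is fitted over common peaks
(both group means positive) by iteratively reweighted least squares
(20 iterations, tolerance $10^{-8}$) and subtracted, so a global
efficiency difference between groups becomes the intercept and is removed.
P-values come from a two-sided Welch $t$ on log2 replicate signal when
both groups have at least two replicates; with single "replicates" the
rescaled values are treated as pseudo-counts and a two-sided Poisson tail
is used (this fallback can be disabled). A peak is differential when
$|M'| > 1$ and $P < 0.05$ — the standard criteria for MA-normalized
comparisons of this kind; both thresholds are arguments.

The comparison is exactly antisymmetric: exchanging the groups negates
every corrected $M$ and swaps the `up_in_A`/`up_in_B` calls, and a
self-comparison yields no calls. Variable peaks can be grouped into
specificity classes with `kmeans_variable_peaks()`: rows are z-scored
(so clusters reflect cross-sample profile shape, not level) and clustered
with `stats::kmeans` using 50 restarts under a fixed seed, which makes
the assignment reproducible without a hand-rolled initializer.

## Chromatin-state dynamics

State tracks are label vectors over fixed 200-bp bins, read from dense
segmentation BEDs (both `E1`-style and numeric labels are accepted). A
bin is *dynamic* when its label differs between two samples. The
per-category change ratio divides the dynamic bins carrying category $c$
in the reference track by all bins carrying $c$ in the reference; because
the orientation is a genuine choice, both directions and their mean are
reported. The 15-state alphabet maps onto five categories (Promoter,
Transcription, Enhancer-like, Repressive, NoSignal) by the default
`CS1-4 / CS5-8 / CS9-11 / CS12-14 / CS15` grouping; training the state
model itself is out of scope — segmentations are inputs.

The variability score of a mark along a design factor is the mean of
$1 - J$ (Jaccard of peak-set base pairs) over all sample pairs that
differ in that factor while every other design column is held fixed; the
unweighted mean over within-stratum pairs is our aggregation choice,
since more than two samples per stratum makes some aggregation necessary.

## Distal peak–gene linking

Candidate pairs are all same-chromosome (distal peak, gene) pairs with
midpoint-to-TSS distance at most 500 kb (closed bound). The anchor —
peak midpoint to TSS — is our choice; it is symmetric and unambiguous.
Each candidate gets the Pearson correlation $r$ between the peak's signal
(FPKM-like) and the gene's expression (TPM) across shared samples. The
null model draws `n_draws = 10000` random peak–gene pairs with the two
partners on *different* chromosomes (degenerate constant-vector draws are
redrawn), and summarises the null correlations by $\mu$ and $\sigma$.
Candidates are scored by $z = (r - \mu)/\sigma$ with the standard-normal
upper-tail p-value: one-sided positive by default, because the linking
logic targets an activating mark; two-sided is a flag. Significance is
raw $p < 0.05$ by default with an optional Benjamini–Hochberg mode
(`bh = TRUE`), which the planted-truth validations use.

The z-based p-value assumes the null correlation distribution is close to
normal. For $n$ exchangeable samples the null $\sigma$ is near
$1/\sqrt{n-1}$; strong shared structure between replicate pairs would
fatten the tails and break calibration, which constrains the synthetic
generator (below) and is equally a caveat for real data with deeply
unbalanced designs.

## Enrichment machinery

All enrichment questions reduce to a 2×2 Fisher exact test
(`fisher_enrichment()`), reported with the sample odds ratio $ad/bc$
(infinite when $bc = 0 < ad$). QTL enrichment contrasts differential vs
stable peaks by QTL overlap (one-sided greater); gene-set overlap tests
build the membership table against a stated universe and also report
observed/expected overlap. BH adjustment is the standard step-up
procedure via `stats::p.adjust`.

The motif scanner scores position weight matrices (JASPAR text I/O;
probability floor $10^{-4}$ per cell before log-odds) on both strands.
Hit calling uses the exact distribution of the log-odds score under the
background model, computed by dynamic programming after discretizing the
score matrix to a lattice of 1/1000 of the total score range; observed
windows are scored on the same integer lattice, so the lookup is exactly
consistent with the null and the only approximation is the initial
rounding (bounded by width × lattice step / 2). `N` bases contribute zero
log-odds. A region-level enrichment then compares regions with ≥ 1 hit
between foreground (dynamic) and background groups with a one-sided
Fisher test and BH across motifs; regions-with-hit, not hit counts, is
the unit because it matches a 2×2 table and is robust to hit clustering.

Cultivar-bias classification marks each gene by whether its promoter
window overlaps (i) DNA-variation intervals, (ii) differential H3K27ac
peaks, (iii) differential H3K27me3 peaks, and summarises the fractions of
differentially expressed genes carrying each evidence layer. DE status
can be imported, or computed by the internal Welch-t test on
log2(TPM + 1) with two selectable presets: FDR < 0.05 with fold-change
≥ 1.5, or adjusted p < 0.05 with |log2 FC| > 1.

## Phenotype formulas

The low-nitrogen response ratio of a root trait is
$\mathrm{LRR} = (R_{LN} - R_{NN})/R_{NN}$; since the design is unpaired,
the per-genotype LRR is computed on group means with a seeded bootstrap
confidence interval (1000 resamples). Nitrate content is $Y = CV/W$ in
µg/g from the colorimetric assay, with a linear standard-curve helper for
OD410 → concentration. Group comparisons default to the pooled-variance
Student $t$ (Welch by flag).

## The synthetic generator

`simulate_epigenome()` emulates the full design: 2 cultivars × 2 nitrogen
conditions × 3 tissues × 2 replicates (24 samples) on 3 × 1 Mb
chromosomes with 240 non-overlapping genes and a 600-peak catalogue.
Signal for peak $i$ in sample $s$ is

$$x_{is} = \max\!\big(b_i + u_{i,\mathrm{cell}(s)} + \varepsilon_{is},\, 0\big),
\qquad b_i \sim \mathrm{LogNormal}(2, 1),$$

with an additive Gaussian per-design-cell effect $u$ (sd 0.7, shared by
replicates — so `noise_sd = 0` makes replicate columns identical) and
per-sample Gaussian noise (sd 1.3). The noise-dominated additive form is
deliberate: it keeps cross-sample variation close to the
independent-Gaussian regime, which is what the z-based link p-values
assume; under it the null p-values are Uniform(0, 1) and the null
$\sigma$ sits within a few percent of $1/\sqrt{n-1}$. Expression uses the
same structure with a LogNormal(3, 1) baseline.

Planted structure, all recorded in a truth object: cultivar-specific
peaks (high in the owner, `specific_fold` lower in the other cultivar;
planted on peaks of at-least-median baseline, since a 4-fold contrast on
a near-background peak cannot clear the $|M|>1$ criterion and "specific"
status there would be meaningless); distal-peak → gene links whose gene
expression is the peak signal plus noise scaled to a target correlation
`link_rho`; divergent state bins planted at an exact count between the
two cultivars' otherwise-identical tracks; GCC-box (`CGCCGCC`, ERF-type)
motif instances planted at 50% of foreground vs 5% of background regions
with a GA-repeat control planted equally in both (plantings never overlap
within a region); cultivar-DE genes (log2 FC ± 2) on unlinked genes; QTL
and TE intervals; and a root-trait table in which cultivar A responds to
LN through root size and volume while cultivar B adds root tips —
contrasting strategies with eight replicates per cell.

What the generator does **not** emulate: read-level sampling noise,
peak-calling artefacts, mark-specific peak-width distributions,
correlated neighbouring peaks, sequence polymorphism between cultivars,
or any genome larger than a few megabases. Passing tests therefore
demonstrate correctness of the computations and calibration under the
stated model, not performance on real wheat-scale data.

## Problem sizes, determinism, degenerate inputs

The validation suite uses fixtures of 100–600 peaks, up to 2 Mb × 3
chromosomes, 10 000 null draws and five-seed averages for recovery rates;
these sizes give stable estimates while keeping a laptop-scale runtime.
One master seed fans out to per-generator child seeds, so any stage can
be rerun independently and the whole pipeline is byte-identical across
reruns with the same configuration (the run log, which records wall-clock
stage timings, is the one file excluded from that guarantee). Degenerate
inputs have defined behaviour throughout: two empty peak sets have
Jaccard 0 (with a message); a category absent from a reference track
yields an `NA` change ratio; constant vectors are flagged `NA` in
correlations and redrawn in the null; an all-`N` sequence yields no motif
hits; single-replicate strata are skipped with a warning in variability
scores.

## Known limitations

The MA p-value scheme replaces the original read-level Bayesian model
with a replicate-level test plus a count fallback, so peaks with very low
baseline and the pseudocount interact: contrasts below roughly the
pseudocount scale are not callable. The link null assumes near-normal
null correlations; heavily structured designs violate this. The bias
classification treats DNA variation as given intervals and does not call
variants. None of the enrichment tests model spatial autocorrelation of
the genome; intervals are treated as exchangeable units.
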