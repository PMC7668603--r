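---
title: "Quantifying exosomal small RNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exosomal small RNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomir)
```

## The problem

Amniotic-fluid exosomes carry a small-RNA cargo dominated by piRNAs
(26–31 nt) with a substantial miRNA fraction (~20–24 nt). Sequencing that
cargo and asking which species respond to a maternal treatment requires a
chain of steps, each with quantitative pitfalls: 3' adapter read-through
(inserts are shorter than the instrument read), heavy multi-mapping (piRNA
loci sit in repeated sequence), imprecise mature ends (a few nt of 5'/3'
heterogeneity), strong technical library-to-library variation (addressed
with spike-ins mixed at a fixed 15:1 sample-to-spike mass ratio before
library prep), and small per-group sample sizes. `exomir` implements this
chain end to end, together with a synthetic-data generator whose ground
truth lets every stage be checked exactly.

## Quantification model

**Trimming.** The 3' adapter is located by semi-global suffix alignment:
among all cut points whose adapter overlap has a mismatch fraction at most
`max_error_rate` (default 0.1) and overlap at least `min_overlap` (default
3 nt), the match with the fewest errors wins, ties going to the longest
overlap (earliest cut). Quality trimming uses the running-sum rule: walking
from the 3' end accumulating `cutoff − q`, the read is cut where the sum
peaks. Inserts outside [15, 45] nt are dropped. The adapter default
`AGATCGGAAGAGC` is the small-RNA kit-family adapter; all parameters are
configurable, since trimming tools' conventions differ in exactly these
defaults.

**Alignment.** Reads are placed end-to-end with at most `v` substitutions
(default 1, no indels — the mismatch-only alignment mode standard for small
RNAs), on both strands, with only the minimal-mismatch stratum reported
(best-stratum semantics) and at most `k = 100` placements per read. The
implementation seeds candidate locations from an exact k-mer index by the
pigeonhole principle: splitting a read into `v + 1` chunks, any placement
with at most `v` mismatches leaves one chunk exact. The default seed length
is 7 because completeness with `v = 1` requires reads at least twice the
seed length and the length filter admits 15 nt inserts; shorter reads (down
to the seed length) fall back to exhaustive scanning. Placements are
ordered canonically (chromosome, start, strand) so truncation at `k` is
deterministic. `n_placements` — the `n` of the 1/n counting rule — is the
retained stratum size before truncation, capped at `k`: that is what a
consumer of the aligner's output can actually observe.

**Assignment and counting.** An alignment is assigned to a mature
annotation when the strands match and, in transcript orientation, its 5'
end lies within −3..+2 nt of the annotated 5' end and its 3' end within
−2..+3 nt of the annotated 3' end, both bounds inclusive. The windows are
strand-oriented rather than genomic-left/right; for mature small RNAs the
5' end is the biologically defined one, so this is the coherent reading.
Each assigned placement contributes `1/n_placements` to its species. When
one placement satisfies the windows of two annotations (possible since
same-strand annotations need only be non-overlapping), it goes to the
annotation with the smaller total end offset `|d5| + |d3|`; exact ties are
split equally, so a placement never contributes more than `1/n`. A read's
total contribution is therefore `n_assigned / n_placements ≤ 1`, with
equality exactly when every placement lands in some annotation. Multi-locus
species (the same species id at several genomic copies) are a single
assignment target, so a read hitting all copies of a repeated species still
contributes exactly 1.

**Spike-ins** are counted by exact sequence identity of the trimmed insert
(no mismatches), mirroring how spike-in reads are usually scored against
their reference.

**Liftover.** piRNA annotations maintained on an older assembly are
remapped through UCSC chain files (via `rtracklayer`). An interval is
rejected when under `min_ratio = 0.95` of its bases map or its image is
split across chromosomes or strands; the accepted image is the span of the
mapped pieces. The 0.95 default keeps near-complete intervals while
rejecting intervals straddling assembly gaps, for which a mature-RNA
coordinate would be meaningless.

## Normalization and testing

**Composition is fixed:** spike-in scaling first, then median-of-ratios
size factors — matching a protocol that normalizes against spike-in
content and library size and then applies a count-based scale factor.
Spike-in normalization computes each library's spike-in rate
`r_j = spike_j / total_mapped_j` and rescales column `j` by
`1e6 · mean(r) / spike_j` — equivalently, counts per million mapped reads
times the ratio of the mean spike rate to the sample's spike rate. Written
this way the transform is invariant to pure depth changes (a library
sequenced twice as deep, spike-ins scaling along, normalizes to the same
column), which is the property the spike-ins exist to provide; composing
"divide by spike-ins" and "divide by total" as two separate steps would
instead double-correct depth.

**Size factors** are the median across all-positive species of the ratio
of a sample's count to the species' geometric mean — the standard
median-of-ratios estimator (species containing zeros are excluded because
their geometric mean is undefined). For the piRNA analysis, size factors
are computed on the miRNA submatrix only and applied to the piRNAs, with
miRNAs removed before testing: miRNAs act as an internal reference class
so that global piRNA shifts are not normalized away.

**Dispersion.** Per-species raw dispersions come from the method of
moments on size-factor-normalized counts, pooled across groups:
`α̂ = (s² − μ̄)/μ̄²`, floored at 0. A parametric trend `a₀ + a₁/μ` is
fitted by iteratively reweighted (bisquare) regression, and the final
estimate shrinks the log raw dispersion toward the log trend with an
empirical-Bayes weight: the prior variance is the excess of the residual
spread (MAD²) over the sampling variance of a raw log-dispersion estimate,
approximated by `trigamma((n − p)/2)`. At n = 3 per group the raw values
are nearly uninformative, so estimates sit close to the trend; with many
samples the raw values dominate. Final dispersions are floored at 1e-8;
all-zero species are excluded and reported.

**Testing.** Each species is fitted with an NB log-link GLM at its final
dispersion, with `log(size factor)` offsets, condition as the contrast and
optionally batch as an additive covariate. The Wald statistic is the
condition coefficient over its standard error; `log2FC` is that
coefficient divided by `log 2`. Two-sided p-values use a **t reference
with the model's residual degrees of freedom** rather than the normal: in
null calibrations at n = 3 vs 3 (dispersion 0.05) the normal reference
rejected about 10% of null species at the 0.05 level, while the t
reference sits near nominal; the two coincide as n grows. BH adjustment is
applied within each class, but the candidate flag follows the *raw*
p < 0.05 rule — the selection rule actually used to pick species for qPCR
verification — with a switch to flag on q instead.

**Class enrichment** (piRNA vs miRNA) is a paired two-sided t-test across
samples of per-class totals, with the 95% CI of the mean paired
difference. Because "enriched in piRNA species" can mean abundance or
richness, both pairings are implemented (`mode = "abundance"` sums
normalized counts; `mode = "richness"` counts detected species).
Zero-variance nonzero differences report a p-value below machine precision
with an explicit warning rather than failing.

**Clustering and label association.** Sample correlations are Pearson on
`log2(x + 1)` over the selected class (the transform and coefficient are
this package's choice; neither is dictated by the protocol being
reproduced). The dendrogram is average linkage on `1 − r`. The label
association score is the mean within-label correlation minus the mean
between-label correlation, with a seeded permutation p-value; it is
invariant to global rescaling of the counts because correlations are.
Candidate selection ranks p ascending, then `|log2FC|` descending, then
species id, truncated to 12 by default.

**qPCR statistics.** ΔCt is target Ct minus reference Ct (RNU1A by
default) with technical replicates averaged first; fold change is
`efficiency^−ΔΔCt` with efficiency fixed at 2 (no standard-curve
calibration is modeled — configurable); group comparisons are one-way
ANOVA **on the ΔCt scale**, which with two groups reduces exactly to the
pooled t-test. ANOVA on ΔCt rather than on folds keeps the test on the
scale where the Gaussian error model is plausible.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale:

* **Species mix.** 150 miRNA (20–24 nt) and 600 piRNA (26–31 nt) species
  by default, with 25% / 75% of the genomic read mass — a piRNA-dominant
  library with several hundred detectable miRNAs, in proportion to what
  these libraries contain. Base abundances are log-normal (sd 1 on the log
  scale) within class.
* **Counts.** Gamma-Poisson: per-sample gamma weights with dispersion
  0.05 around the per-species mean, reads drawn multinomially so each
  library totals exactly `depth_per_sample` (200k by default — the study
  scale of ~10M reads is scaled down for desk runs; the acceptance
  calibrations state their own sizes). Spike-in totals are
  `Binomial(depth, 1/16)`: a 15:1 sample-to-spike mass ratio.
* **Effects.** Treatment multiplies planted species' means by `2^lfc` in
  the treated group (12 miRNA species at |log2FC| = 2 by default — the
  planted *fraction*, under a tenth of the miRNA class, matters: planting
  a large fraction would let treatment dominate the correlation structure,
  contradicting the batch-dominant clustering the generator is meant to
  reproduce). The batch effect is a per-(species, batch) Gaussian shift
  on log2 means with sd 0.5, applied to every species — collectively
  stronger than the localized treatment signal.
* **Reads.** Each read is its species' mature sequence with independent
  5'/3' end offsets drawn from a jitter distribution (60% exact, down to
  1% at ±4 nt — some mass deliberately outside the ±3/±2 acceptance
  windows so the filtering is exercised), the 3' adapter appended,
  truncation to 50 nt, and substitution errors at 0.001/base. Multi-locus
  species pick a copy uniformly per read. Repeated ~40 nt cassettes pasted
  into the random genome create genuine multi-mapping; species planted
  inside a cassette keep a 4 nt margin so every jittered read still maps
  to every copy.
* **Ground truth** records every read's source species, applied offsets
  and error-free placement count, plus the realized count matrix — the
  end-to-end oracle: with zero jitter and zero error the full pipeline
  must reproduce the truth counts *exactly*.

What the generator does **not** model: ligation and sequence bias, UMI
structure, RNA secondary structure, indels, quality-score degradation
profiles, or exosome biology. Passing tests therefore demonstrate the
correctness of the quantification and inference machinery under the
declared generative model, not robustness to every artefact of real
libraries.

## Numerical and degenerate-case choices

* Fractional counts (from 1/n weighting) are non-integer; the NB GLM's
  IRLS handles them without modification.
* Cassette copy numbers are powers of two in the validation designs, so
  1/n weights sum without floating-point residue and exact-equality
  oracles are meaningful; the general code path does not rely on this.
* Adapter-match ties, placement-order ties, ambiguous-assignment ties and
  candidate-rank ties all have documented deterministic tie-breaks, so
  identical seeds give byte-identical outputs.
* Zero spike-ins, all-zero species, zero-variance samples, missing qPCR
  references, single-sample labels and empty annotation sets each have a
  defined behaviour (hard error, exclusion-with-report, or warning), never
  silent propagation.

## Validation sizes

The shipped checks use: one 200k-read zero-jitter run for the exact
end-to-end oracle; 1000 random reads on a 100 kb genome against
brute-force mismatch scanning (v ∈ {0,1}); a 10k-read library against the
exhaustive placement×annotation double loop; 2000 null species for type-I
calibration; 200 replicates of 40-species designs for sensitivity/sign
recovery; 100 calibration replicates behind the normalization-invariance
band (worst pairwise median |log2 ratio| stayed below 0.09; the acceptance
band is 0.12); and 50–100 replicates for the batch-vs-treatment clustering
contrast. These sizes are the package's validation design and are chosen
to estimate each quantity stably.

## Known limitations

* The aligner targets desk-scale genomes (up to a few Mb); it is a
  contract-faithful reimplementation of mismatch-only best-stratum
  alignment, not a performance substitute for a production aligner.
* Dispersion shrinkage is a simplified empirical-Bayes scheme; exact
  numerical parity with any particular DE package is a non-goal (a
  cross-check test confirms close agreement of fold changes and sign).
* Whether the historical analysis applied assignment windows genomically
  or strand-oriented, and how it handled batch in the model, is not
  recoverable from the protocol text; this package documents its choices
  (strand-oriented windows; batch as an optional additive covariate,
  default on) and exposes both batch modes.
* The paired enrichment test is reported for both abundance and richness
  pairings because the protocol statement is ambiguous between them.
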