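# exomir

Quantification and differential expression of exosomal small RNAs
(miRNA and piRNA) from small RNA-seq, for researchers analysing
extracellular-vesicle cargo — e.g. amniotic-fluid exosomes in a fetal
alcohol exposure model — where piRNAs dominate the library, multi-mapping
is pervasive, and spike-ins anchor the normalization.

The package implements the full chain as tested R functions, plus a
synthetic-data generator with machine-readable ground truth:

1. **Preprocessing** — 3' adapter removal by semi-global suffix alignment,
   running-sum quality trimming, length filtering (15–45 nt inserts).
2. **Alignment** — end-to-end placement with at most *v* substitutions
   (default 1), both strands, best-stratum reporting capped at *k* = 100
   placements per read, over an exact k-mer index (Rcpp).
3. **Assignment & counting** — an alignment is assigned to a mature
   annotation when, strand-oriented, its 5' end lies in [−3, +2] nt of the
   annotated start and its 3' end in [−2, +3] nt of the annotated end;
   a read with *n* placements contributes 1/*n* per assigned placement:

   count(species *s*) = Σ_reads Σ_placements 1{placement assigned to *s*} / *n*

4. **Liftover** — piRNA annotations remapped between assemblies through
   UCSC chain files, rejected below a 95% mapped-base ratio.
5. **Normalization & DE** — spike-in scaling relative to library size,
   median-of-ratios size factors, NB dispersions (method of moments →
   1/mean trend → empirical-Bayes shrinkage), per-species NB Wald tests
   per timepoint (EtOH vs control; batch optionally a covariate); piRNAs
   are normalized against miRNA counts with miRNAs removed. Candidates
   are flagged at raw p < 0.05, the rule used to pick species for qPCR
   verification; BH q-values are reported alongside.
6. **Clustering & reporting** — Pearson correlations of
   log2(normalized + 1), average-linkage dendrograms on 1 − r,
   permutation-tested label association (batch / treatment / timepoint),
   candidate selection (p, then |log2FC|).
7. **qPCR statistics** — ΔCt against a reference assay (RNU1A), 2^−ΔΔCt
   fold changes, one-way ANOVA on ΔCt, standard errors.

## Worked example

```r
library(exomir)

design <- simulation_design(n_samples_per_group = 3,
                            depth_per_sample = 30000L,
                            n_planted = 9L, seed = 1)
cfg <- run_config(design = design, seed = 1)
res <- run_pipeline(cfg, "demo_run")

res$counts
#> exomir count matrix: 750 species x 12 samples (raw counts)
#> classes: miRNA=150, piRNA=600

res$class_enrichment[c("t", "p_value")]
#> piRNA vs miRNA paired t = 50.5, p = 2.2e-14

sapply(res$label_association, `[[`, "score")
#> batch 0.125 (p = 0.002)   treatment 0.035 (p = 0.055)   ...

head(res$candidates[, .(timepoint, species_id, log2fc, p_value, direction)], 3)
#>    timepoint  species_id log2fc p_value direction
#> 1:       E19 miR-sim-001   1.61 9.4e-05        up
#> 2:       E16 miR-sim-007   2.30 2.5e-04        up
#> 3:       E16 miR-sim-009   2.00 6.4e-04        up
```

Reading the output: the paired t-test confirms the piRNA class dominates
every library (the generator plants a 75/25 piRNA/miRNA mass split); the
label-association scores show the batch ("experiment") effect structuring
the sample correlations while the treatment does not reach significance —
the treatment signal lives in only 9 of 150 miRNA species; and the
candidate table lists those planted species recovered at raw p < 0.05 with
their estimated log2 fold changes (planted at ±2).

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_qpcr.R`), each a thin driver over the
package functions; they write bulky intermediates to `scratch/` and small
summary tables to `results/`.

## Package layout

```
R/                 implementation (one file per stage)
src/               Rcpp core: k-mer index, aligner, trimming primitives
analysis/          numbered narrative drivers over the package
scripts/           acceptance script
tests/testthat/    unit, property and acceptance tests with in-code oracles
vignettes/         methods vignette (models, parameters, design choices)
inst/extdata/      small synthetic fixtures (labelled as such)
```
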