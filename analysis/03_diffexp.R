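#!/usr/bin/env Rscript
# Stage 3: normalization, class enrichment and differential expression.
#
# Spike-in normalization relative to library size, the paired piRNA-vs-miRNA
# class-enrichment t-test, then per-timepoint NB Wald contrasts (EtOH vs
# control, batch as an additive covariate): miRNAs with their own
# median-of-ratios size factors, piRNAs normalized against the miRNA counts
# with miRNAs removed. Candidates are flagged at raw p < 0.05, the selection
# rule used for downstream qPCR verification.

suppressPackageStartupMessages({
  library(exomir)
  library(data.table)
})

m <- read_count_matrix("scratch/analysis/counts_raw.tsv")
ss <- read_sample_sheet("scratch/analysis/sim/sample_sheet.tsv")

mn <- spikein_normalize(m)
enr <- class_enrichment_test(mn)
cat(sprintf("class enrichment (piRNA vs miRNA totals): t = %.2f, p = %.3g, 95%% CI [%.0f, %.0f]\n",
            enr$t, enr$p_value, enr$conf_int[1], enr$conf_int[2]))

de_all <- list()
for (tp in unique(ss$timepoint)) {
  sel <- ss$timepoint == tp
  sub <- exomir:::new_count_matrix(mn$counts[, sel, drop = FALSE], mn$class,
                                   mn$total_mapped[sel], mn$spikein_counts[sel],
                                   normalized = TRUE)
  grp <- ss$condition[sel]; bt <- ss$batch[sel]
  mi <- names(sub$class)[sub$class == "miRNA"]
  sub_mi <- exomir:::new_count_matrix(sub$counts[mi, , drop = FALSE],
                                      sub$class[mi], sub$total_mapped,
                                      sub$spikein_counts, normalized = TRUE)
  de_mi <- nb_wald_test(sub_mi, grp, baseline = "control", batch = bt)
  de_pi <- pirna_specific_pipeline(sub, grp, baseline = "control", batch = bt)
  de_all[[tp]] <- rbind(cbind(timepoint = tp, de_mi), cbind(timepoint = tp, de_pi))
  cat(sprintf("%s: %d/%d miRNA and %d/%d piRNA species at p < 0.05\n",
              tp, sum(de_mi$candidate), nrow(de_mi),
              sum(de_pi$candidate), nrow(de_pi)))
}
de <- rbindlist(de_all)
fwrite(de[candidate == TRUE][order(p_value)],
       "results/03_de_candidates_full.tsv", sep = "\t")

cand <- select_candidates(de[class == "miRNA"], max_candidates = 12)
fwrite(cand[, .(timepoint, species_id, log2fc = round(log2fc, 3),
                p_value = signif(p_value, 3), q_value = signif(q_value, 3),
                direction)],
       "results/03_candidates_miRNA.tsv", sep = "\t")
cat(sprintf("selected %d miRNA validation candidates (p then |log2FC| ranking)\n",
            nrow(cand)))
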