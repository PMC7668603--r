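#!/usr/bin/env Rscript
# Stage 5: qPCR verification statistics.
#
# Delta-Ct against the RNU1A reference assay (technical triplicates averaged),
# 2^-ddCt fold changes (EtOH vs control) and one-way ANOVA per target, on the
# package's synthetic Ct fixture (the study's Ct tables are not public; the
# fixture plants known expression shifts).

suppressPackageStartupMessages({
  library(exomir)
  library(data.table)
})

ct_path <- system.file("extdata", "synthetic_ct_table.tsv", package = "exomir")
res <- qpcr_analysis(ct_path, reference = "RNU1A", control = "control")
res_out <- res[, .(target_id,
                   mean_dct_control = round(mean_dct_control, 2),
                   se_dct_control = round(se_dct_control, 3),
                   ddct = round(ddct, 3), fold = round(fold, 3),
                   F = round(F, 2), p_value = signif(p_value, 3))]
fwrite(res_out, "results/05_qpcr_results.tsv", sep = "\t")
print(res_out)
cat(sprintf("%d/%d targets significant by one-way ANOVA at p < 0.05\n",
            sum(res$p_value < 0.05), nrow(res)))
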