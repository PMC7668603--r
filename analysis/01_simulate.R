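#!/usr/bin/env Rscript
# Stage 1: simulate the study's small-RNA libraries.
#
# Desk-scale stand-in for the deposited sequencing data: 12 libraries
# (2 conditions x 2 timepoints x 3 replicates, split over 2 experimental
# batches), piRNA-dominant species mix, spike-ins at a 15:1 mass ratio,
# 12 planted miRNA fold changes, and a batch effect stronger than the
# treatment effect. Reads, ground truth and references go to
# scratch/analysis/ (bulky); a small design summary goes to results/.

suppressPackageStartupMessages({
  library(exomir)
  library(data.table)
})

seed <- 1L
ref_dir <- "scratch/analysis/ref"
sim_dir <- "scratch/analysis/sim"
dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

design <- simulation_design(
  n_samples_per_group = 3,
  depth_per_sample = 30000L,             # desk-scale depth
  n_planted = 9L,                        # planted miRNA effects at |log2FC| 2
  seed = seed
)

genome <- generate_genome(seed, chrom_lengths = c(60000L, 40000L),
                          n_repeat_families = 4, repeat_copies = 4)
ann <- plant_annotations(genome, design, seed = seed)
spike <- generate_spikeins(genome, seed = seed)

write_fasta(genome$seq, file.path(ref_dir, "genome.fa"))
write_fasta(spike, file.path(ref_dir, "spikeins.fa"))
write_annotations_bed(ann, file.path(ref_dir, "annotations.bed"))

sim <- simulate_libraries(genome, ann, spike, design, outdir = sim_dir,
                          seed = seed)

summary <- merge(
  sim$sample_sheet,
  data.table(sample = colnames(sim$truth$counts),
             genomic_reads = colSums(sim$truth$counts),
             spikein_reads = colSums(sim$truth$spike_counts)),
  by = "sample")
fwrite(summary, "results/01_design_summary.tsv", sep = "\t")

cat(sprintf(
  "simulated %d libraries x %d reads (%d miRNA, %d piRNA species; %d planted effects)\n",
  nrow(sim$sample_sheet), design$depth_per_sample, design$n_mirna,
  design$n_pirna, length(sim$truth$planted_fc)))
cat(sprintf("spike-in fraction: expected %.4f, realised %.4f\n",
            design$spikein_mass_fraction,
            mean(summary$spikein_reads / design$depth_per_sample)))
cat("references in", ref_dir, "| reads + truth in", sim_dir, "\n")
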