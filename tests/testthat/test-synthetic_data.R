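test_that("generated genomes contain each cassette at the requested copy number", {
  g1 <- generate_genome(7, chrom_lengths = c(5000, 3000),
                        n_repeat_families = 3, repeat_copies = 1)
  for (f in names(g1$family_seq)) {
    hits <- sum(Biostrings::vcountPattern(g1$family_seq[[f]], g1$seq))
    expect_equal(hits, 1)
  }

  g4 <- generate_genome(7, chrom_lengths = c(20000, 12000),
                        n_repeat_families = 2, repeat_copies = 4)
  # a 22-mer drawn wholly inside a cassette occurs exactly 4 times
  kmer <- substr(g4$family_seq[[1]], 5, 26)
  hits <- sum(Biostrings::vcountPattern(kmer, g4$seq))
  expect_equal(hits, 4)
  expect_equal(nrow(g4$cassettes), 8)
})

test_that("genome generation is deterministic and fails on impossible packing", {
  g1 <- generate_genome(11, chrom_lengths = c(4000), n_repeat_families = 2,
                        repeat_copies = 2)
  g2 <- generate_genome(11, chrom_lengths = c(4000), n_repeat_families = 2,
                        repeat_copies = 2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$seq, f1); write_fasta(g2$seq, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(generate_genome(1, chrom_lengths = c(1000),
                               n_repeat_families = 10, repeat_copies = 10),
               "too short")
})

test_that("planted annotations respect counts, length ranges and non-overlap", {
  w <- make_small_world(seed = 5, n_mirna = 50, n_pirna = 200)
  ann <- w$ann
  expect_equal(length(unique(ann$species_id)), 250)
  len <- ann$end - ann$start
  expect_true(all((len >= 20 & len <= 24) | (len >= 26 & len <= 31)))
  expect_true(all((len >= 20 & len <= 24)[ann$class == "miRNA"]))
  expect_true(all((len >= 26 & len <= 31)[ann$class == "piRNA"]))
  # non-overlap on the same strand
  for (st in c("+", "-")) {
    a <- ann[strand == st][order(chrom, start)]
    same_chrom <- a$chrom[-1] == a$chrom[-nrow(a)]
    expect_true(all(a$start[-1][same_chrom] >= a$end[-nrow(a)][same_chrom]))
  }
  # a multi-locus (cassette) species' sequence occurs >= copies times
  multi <- ann[, .N, by = species_id][N > 1]
  expect_gt(nrow(multi), 0)
  sp <- multi$species_id[1]
  seqs <- annotation_sequences(w$genome, ann[species_id == sp])
  expect_true(all(seqs == seqs[1]))
  hits <- sum(Biostrings::vcountPattern(seqs[[1]], w$genome$seq)) +
    sum(Biostrings::vcountPattern(
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[[1]]))),
      w$genome$seq))
  expect_gte(hits, multi$N[1])
})

test_that("zero species requested yields an empty annotation set", {
  g <- generate_genome(3, chrom_lengths = c(2000), n_repeat_families = 1,
                       repeat_copies = 1)
  d <- simulation_design(n_mirna = 0, n_pirna = 0, n_planted = 0)
  ann <- plant_annotations(g, d)
  expect_equal(nrow(ann), 0)
})

test_that("spike-ins have no exact genomic match", {
  w <- make_small_world(seed = 9)
  for (s in w$spike) {
    p <- Biostrings::DNAString(s)
    hits <- sum(Biostrings::vcountPattern(p, w$genome$seq)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), w$genome$seq))
    expect_equal(hits, 0)
  }
})

test_that("simulated libraries conserve depth exactly and are deterministic", {
  w <- make_small_world(seed = 21, depth = 3000L)
  s1 <- simulate_libraries(w$genome, w$ann, w$spike, w$design, seed = 21)
  s2 <- simulate_libraries(w$genome, w$ann, w$spike, w$design, seed = 21)
  for (smp in names(s1$reads)) {
    expect_equal(nrow(s1$reads[[smp]]), w$design$depth_per_sample)
    expect_identical(s1$reads[[smp]], s2$reads[[smp]])
  }
  expect_identical(s1$truth$reads, s2$truth$reads)
  # truth counts + spike counts account for every read
  tot <- colSums(s1$truth$counts) + colSums(s1$truth$spike_counts)
  expect_true(all(tot == w$design$depth_per_sample))
})

test_that("zero jitter, zero error, no adapter reproduces mature sequences", {
  w <- make_small_world(seed = 13, depth = 2000L, adapter = "")
  sim <- simulate_libraries(w$genome, w$ann, w$spike, w$design, seed = 13)
  seqs <- annotation_sequences(w$genome, unique(w$ann, by = "species_id"))
  rd <- sim$reads[[1]]
  tr <- sim$truth$reads[sample == names(sim$reads)[1]]
  genomic <- tr$class != "spikein"
  expect_identical(rd$seq[genomic], unname(seqs[tr$source_id[genomic]]))
  expect_identical(rd$seq[!genomic], unname(w$spike[tr$source_id[!genomic]]))
})

test_that("planted fold changes land in the Monte-Carlo band on raw counts", {
  # one species at +2 log2, dispersion 0.05, depth 200k, 3 vs 3:
  # group mean ratio within [3.0, 5.3]
  d <- simulation_design(n_samples_per_group = 3, timepoints = "E16",
                         depth_per_sample = 200000L, dispersion = 0.05,
                         n_planted = 0L, seed = 31)
  g <- generate_genome(31, chrom_lengths = c(30000, 20000),
                       n_repeat_families = 2, repeat_copies = 3)
  ann <- plant_annotations(g, d, seed = 31)
  target <- ann[class == "miRNA", species_id][1]
  d$planted_fc <- setNames(2, target)
  sim <- simulate_counts(d, ann, seed = 31)
  ss <- sim$sample_sheet
  trt <- rowMeans(sim$counts[target, ss$condition == "EtOH", drop = FALSE])
  ctl <- rowMeans(sim$counts[target, ss$condition == "control", drop = FALSE])
  ratio <- trt / ctl
  expect_gte(ratio, 3.0)
  expect_lte(ratio, 5.3)
})

test_that("unknown species in planted_fc is a hard error", {
  w <- make_small_world(seed = 2)
  w$design$planted_fc <- c(nonexistent = 2)
  expect_error(simulate_counts(w$design, w$ann), "unknown species")
})

test_that("spike-in read totals follow the binomial expectation", {
  d <- simulation_design(n_samples_per_group = 2, timepoints = "E16",
                         depth_per_sample = 160000L,
                         spikein_mass_fraction = 1 / 16, seed = 8)
  g <- generate_genome(8, chrom_lengths = c(20000), n_repeat_families = 1,
                       repeat_copies = 2)
  ann <- plant_annotations(g, d, seed = 8)
  spike <- generate_spikeins(g, seed = 8)
  sim <- simulate_counts(d, ann, spike, seed = 8)
  expected <- 160000 / 16
  for (j in seq_len(ncol(sim$spike_counts))) {
    expect_lt(abs(sum(sim$spike_counts[, j]) - expected), 3 * sqrt(expected))
  }
})

test_that("piRNA mass dominates miRNA mass in every sample under the default design", {
  w <- make_small_world(seed = 17, depth = 20000L, n_mirna = 20, n_pirna = 80)
  sim <- simulate_counts(w$design, w$ann, w$spike, seed = 17)
  cls <- classify_species(rownames(sim$counts))
  pir <- colSums(sim$counts[cls == "piRNA", ])
  mir <- colSums(sim$counts[cls == "miRNA", ])
  expect_true(all(pir > mir))
})
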