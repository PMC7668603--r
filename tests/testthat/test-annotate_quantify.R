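test_that("fuzzy-window assignment honours strand-oriented boundary-inclusive offsets", {
  w <- assignment_windows()
  ann <- list(chrom = "chr1", start = 100L, end = 122L, strand = "+")
  mk <- function(s, e, st = "+", ch = "chr1")
    list(chrom = ch, start = s, end = e, strand = st)
  # exact coincidence
  expect_true(assign_alignment(mk(100, 122), ann, w))
  # 5' offset -3 and 3' offset +3 are boundary-inclusive
  expect_true(assign_alignment(mk(97, 125), ann, w))
  # 5' offset +3 exceeds +2
  expect_false(assign_alignment(mk(103, 122), ann, w))
  # 3' offset -3 below -2
  expect_false(assign_alignment(mk(100, 119), ann, w))
  # strand mismatch
  expect_false(assign_alignment(mk(100, 122, "-"), ann, w))
  # chromosome mismatch
  expect_false(assign_alignment(mk(100, 122, ch = "chr2"), ann, w))

  # minus-strand annotation: 5' end is the genomic end
  annm <- list(chrom = "chr1", start = 200L, end = 226L, strand = "-")
  expect_true(assign_alignment(mk(200, 226, "-"), annm, w))
  # 5' offset -3 moves the genomic end up by 3; 3' offset +3 moves start down
  expect_true(assign_alignment(mk(197, 229, "-"), annm, w))
  # genomic end +3 means 5' offset -3 (allowed); end -3 means +3 (too far in)
  expect_false(assign_alignment(mk(200, 223, "-"), annm, w))
})

test_that("widening the windows never decreases assignment", {
  set.seed(77)
  w_narrow <- assignment_windows()
  w_wide <- assignment_windows(-4, 3, -3, 4)
  ann <- data.table(species_id = sprintf("miR-sim-%03d", 1:5), class = "miRNA",
                    chrom = "chr1", start = seq(100L, 900L, 200L),
                    end = seq(100L, 900L, 200L) + 22L, strand = "+")
  rec <- data.table(read_id = sprintf("r%d", 1:200),
                    chrom = "chr1",
                    start = sample(90:930, 200, replace = TRUE),
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    mismatches = 0L, n_placements = 1L)
  rec[, end := start + 22L]
  c1 <- count_sample(rec, ann, w_narrow)$counts
  c2 <- count_sample(rec, ann, w_wide)$counts
  expect_true(all(c2 >= c1))
})

test_that("multi-mapped mass is distributed 1/n per placement", {
  ann <- data.table(
    species_id = c("miR-sim-A", "miR-sim-A", "miR-sim-B"), class = "miRNA",
    chrom = "chr1", start = c(100L, 300L, 500L), end = c(122L, 322L, 522L),
    strand = "+"
  )
  # one read with 4 placements: two assigned to A (its two loci), one to B,
  # one matching nothing
  rec <- data.table(
    read_id = "r1", chrom = "chr1",
    start = c(100L, 300L, 500L, 700L), end = c(122L, 322L, 522L, 722L),
    strand = "+", mismatches = 0L, n_placements = 4L
  )
  res <- count_sample(rec, ann)
  expect_equal(unname(res$counts["miR-sim-A"]), 0.5)
  expect_equal(unname(res$counts["miR-sim-B"]), 0.25)
  expect_equal(res$assigned_mass, 0.75)

  # a uniquely mapped read adds exactly 1
  rec1 <- data.table(read_id = "r2", chrom = "chr1", start = 100L, end = 122L,
                     strand = "+", mismatches = 0L, n_placements = 1L)
  res1 <- count_sample(rec1, ann)
  expect_equal(unname(res1$counts["miR-sim-A"]), 1.0)
})

test_that("overlapping-window ambiguity resolves to the nearest annotation, ties split", {
  w <- assignment_windows()
  ann <- data.table(
    species_id = c("miR-sim-X", "miR-sim-Y"), class = "miRNA",
    chrom = "chr1", start = c(100L, 102L), end = c(122L, 124L), strand = "+"
  )
  # read exactly on X: distance 0 vs 4 -> all mass to X
  rec <- data.table(read_id = "r1", chrom = "chr1", start = 100L, end = 122L,
                    strand = "+", mismatches = 0L, n_placements = 1L)
  res <- count_sample(rec, ann, w)
  expect_equal(unname(res$counts["miR-sim-X"]), 1)
  expect_equal(unname(res$counts["miR-sim-Y"]), 0)
  expect_equal(res$ambiguous_placements, 1L)
  # read equidistant between X and Y -> split
  rec2 <- data.table(read_id = "r2", chrom = "chr1", start = 101L, end = 123L,
                     strand = "+", mismatches = 0L, n_placements = 1L)
  res2 <- count_sample(rec2, ann, w)
  expect_equal(unname(res2$counts["miR-sim-X"]), 0.5)
  expect_equal(unname(res2$counts["miR-sim-Y"]), 0.5)
})

test_that("count_sample equals the exhaustive double-loop oracle on simulated data", {
  w <- make_small_world(seed = 55, depth = 4000L, jitter = DEFAULT_JITTER)
  sim <- simulate_libraries(w$genome, w$ann, w$spike, w$design, seed = 55)
  smp <- names(sim$reads)[1]
  pp <- preprocess_reads(sim$reads[[smp]])
  idx <- build_index(w$genome, seed_length = 7)
  alns <- align_reads(pp$reads, idx, aligner_params(v = 1))
  got <- count_sample(alns, w$ann)
  want <- oracle_count(alns, w$ann)
  expect_equal(got$counts[sort(names(got$counts))],
               want[sort(names(want))], tolerance = 1e-12)
  # per-read mass conservation: each read contributes at most 1
  per_read <- alns[, .(n = .N, np = n_placements[1]), by = read_id]
  expect_true(all(per_read$n <= per_read$np))
  expect_lte(got$assigned_mass, got$total_mapped + 1e-9)
})

test_that("zero-jitter zero-error quantification reproduces the truth exactly", {
  w <- make_small_world(seed = 61, depth = 3000L)
  sim <- simulate_libraries(w$genome, w$ann, w$spike, w$design, seed = 61)
  idx <- build_index(w$genome, seed_length = 7)
  for (smp in names(sim$reads)[1:2]) {
    pp <- preprocess_reads(sim$reads[[smp]])
    alns <- align_reads(pp$reads, idx, aligner_params(v = 1))
    res <- count_sample(alns, w$ann)
    truth <- sim$truth$counts[, smp]
    expect_equal(res$counts[names(truth)], truth + 0.0, tolerance = 1e-9)
  }
})

test_that("spike-in counting is exact-match only", {
  spk <- c("spike-01" = "ACGTACGTACGTACGTACGTA", "spike-02" = "TTGGCCAACCGGTTAACCGGA")
  rd <- data.table(id = c("a", "b", "c", "d"),
                   seq = c(spk[[1]], spk[[2]], sub("^A", "C", spk[[1]]), "ACGT"),
                   qual = c(strrep("I", 21), strrep("I", 21), strrep("I", 21), "IIII"))
  res <- count_spikeins(rd, spk)
  expect_equal(unname(res$counts), c(1L, 1L))
  expect_equal(res$total, 2L)
})

test_that("merge_counts orders samples per sheet and zero-fills", {
  ann <- data.table(species_id = c("miR-sim-1", "miR-sim-2", "piR-sim-1"),
                    class = c("miRNA", "miRNA", "piRNA"),
                    chrom = "chr1", start = c(0L, 100L, 200L),
                    end = c(22L, 122L, 228L), strand = "+")
  ss <- data.table(sample = c("s1", "s2"), condition = c("a", "b"),
                   batch = "x", timepoint = "t")
  cols <- list(
    s2 = list(counts = c("miR-sim-1" = 5), total_mapped = 10),
    s1 = list(counts = c("miR-sim-1" = 1, "piR-sim-1" = 2), total_mapped = 7)
  )
  m <- merge_counts(cols, ss, ann, spikein_totals = c(s1 = 3, s2 = 4))
  expect_equal(colnames(m$counts), c("s1", "s2"))
  expect_equal(m$counts["miR-sim-2", ], c(s1 = 0, s2 = 0))
  expect_equal(m$counts["piR-sim-1", ], c(s1 = 2, s2 = 0))
  expect_equal(unname(m$total_mapped), c(7, 10))
  # permuted input gives the identical matrix
  m2 <- merge_counts(rev(cols), ss, ann, spikein_totals = c(s2 = 4, s1 = 3))
  expect_identical(m$counts, m2$counts)
  expect_error(merge_counts(c(cols, cols[1]), ss, ann), "duplicate")
  # round-trip through TSV + sidecar
  p <- tempfile(fileext = ".tsv")
  write_count_matrix(m, p)
  back <- read_count_matrix(p)
  expect_equal(back$counts, m$counts)
  expect_equal(back$total_mapped, m$total_mapped)
  expect_equal(back$spikein_counts, m$spikein_counts)
})

test_that("identity and offset chains lift intervals exactly", {
  iv <- data.table(species_id = "piR-sim-0001", class = "piRNA",
                   chrom = "chrA", start = 50L, end = 76L, strand = "+")
  ident <- write_chain(tempfile(fileext = ".chain"),
                       "chrA", 1000, 0, 1000, "chrA", 1000, "+", 0, 1000,
                       list(1000))
  r <- liftover_intervals(iv, ident)
  expect_equal(nrow(r$lifted), 1)
  expect_equal(r$lifted$start, 50L)
  expect_equal(r$lifted$end, 76L)

  off <- write_chain(tempfile(fileext = ".chain"),
                     "chrA", 1000, 0, 1000, "chrB", 1100, "+", 100, 1100,
                     list(1000))
  r2 <- liftover_intervals(iv, off)
  expect_equal(r2$lifted$chrom, "chrB")
  expect_equal(r2$lifted$start, 150L)
  expect_equal(r2$lifted$end, 176L)
})

test_that("an interval straddling a chain deletion gap is rejected by min_ratio", {
  # 26 nt interval [10,36) over a chain with a 10 nt source gap after 20
  # aligned bases: 16/26 map, below 0.95
  gap <- write_chain(tempfile(fileext = ".chain"),
                     "chrA", 1000, 0, 130, "chrB", 1000, "+", 0, 120,
                     list(c(20, 10, 0), 100))
  iv <- data.table(species_id = "piR-sim-0002", class = "piRNA",
                   chrom = "chrA", start = 10L, end = 36L, strand = "+")
  r <- liftover_intervals(iv, gap, min_ratio = 0.95)
  expect_equal(nrow(r$lifted), 0)
  expect_match(r$rejected$reason, "below")
  # the same interval passes at a permissive ratio, spanning the gap image
  r2 <- liftover_intervals(iv, gap, min_ratio = 0.5)
  expect_equal(nrow(r2$lifted), 1)
  expect_equal(r2$lifted$start, 10L)
  expect_equal(r2$lifted$end, 26L)
})

test_that("malformed chain files raise a parse error", {
  bad <- tempfile(fileext = ".chain")
  writeLines(c("chain oops", "not blocks"), bad)
  expect_error(liftover_intervals(
    data.table(species_id = "x", class = "piRNA", chrom = "chrA",
               start = 0L, end = 10L, strand = "+"), bad), "malformed|parse")
})
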