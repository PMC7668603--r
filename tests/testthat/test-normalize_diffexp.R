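mk_counts <- function(counts, class = NULL, total = NULL, spike = NULL) {
  if (is.null(class)) class <- setNames(rep("miRNA", nrow(counts)), rownames(counts))
  if (is.null(total)) total <- setNames(colSums(counts), colnames(counts))
  if (is.null(spike)) spike <- setNames(rep(100, ncol(counts)), colnames(counts))
  exomir:::new_count_matrix(counts, class, total, spike)
}

test_that("spike-in normalization is invariant to proportional depth changes", {
  x <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
              dimnames = list(c("miR-sim-1", "miR-sim-2", "miR-sim-3"),
                              c("A", "B")))
  # B is A at exactly 2x depth with spike-ins scaling along
  m <- mk_counts(x, total = c(A = 1000, B = 2000), spike = c(A = 50, B = 100))
  mn <- spikein_normalize(m)
  expect_equal(mn$counts[, "A"], mn$counts[, "B"])

  # identical spike totals and depths: columns change by one common constant
  m2 <- mk_counts(x, total = c(A = 1000, B = 1000), spike = c(A = 50, B = 50))
  mn2 <- spikein_normalize(m2)
  ratio <- mn2$counts / m2$counts
  expect_lt(diff(range(ratio)), 1e-9)

  bad <- mk_counts(x, spike = c(A = 50, B = 0))
  expect_error(spikein_normalize(bad), "sample.*B|B.*sample")
})

test_that("median-of-ratios size factors match hand-computed values", {
  # geometric means (8, 2); ratio medians 0.5 and 2.0
  x <- matrix(c(4, 1, 16, 4), nrow = 2,
              dimnames = list(c("s1", "s2"), c("A", "B")))
  sf <- size_factors_median_of_ratios(x)
  expect_equal(unname(as.numeric(sf)), c(0.5, 2.0))

  # proportional columns give factors proportional to the constants
  v <- c(3, 7, 11, 5)
  y <- cbind(A = v, B = 2 * v, C = 4 * v)
  rownames(y) <- sprintf("sp%d", 1:4)
  sfy <- as.numeric(size_factors_median_of_ratios(y))
  expect_equal(sfy / sfy[1], c(1, 2, 4))

  # single sample: factor 1
  single <- matrix(v, ncol = 1, dimnames = list(sprintf("sp%d", 1:4), "only"))
  expect_equal(unname(as.numeric(size_factors_median_of_ratios(single))), 1)

  # no species with all-positive counts
  z <- matrix(c(0, 1, 1, 0), nrow = 2, dimnames = list(c("a", "b"), c("A", "B")))
  expect_error(size_factors_median_of_ratios(z), "all-positive")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  set.seed(19)
  # Poisson counts (true dispersion 0), 6 per group
  mu <- exp(rnorm(400, log(200), 1))
  xp <- t(vapply(mu, function(m) rpois(12, m), numeric(12)))
  rownames(xp) <- sprintf("sp%d", seq_along(mu))
  colnames(xp) <- sprintf("s%d", 1:12)
  grp <- rep(c("a", "b"), each = 6)
  dp <- estimate_dispersions(xp, grp)
  expect_lt(median(dp$final_dispersion, na.rm = TRUE), 0.05)

  # NB alpha = 0.2 at mean 500, n = 20
  xn <- t(vapply(seq_len(400), function(i)
    rnbinom(20, mu = 500, size = 1 / 0.2), numeric(20)))
  rownames(xn) <- sprintf("sp%d", 1:400)
  colnames(xn) <- sprintf("s%d", 1:20)
  dn <- estimate_dispersions(xn, rep(c("a", "b"), each = 10))
  expect_gt(mean(dn$raw_dispersion, na.rm = TRUE), 0.1)
  expect_lt(mean(dn$raw_dispersion, na.rm = TRUE), 0.3)

  # constant counts: raw dispersion 0, final positive (trend shrink, floored)
  xc <- matrix(50, 5, 6, dimnames = list(sprintf("sp%d", 1:5), sprintf("s%d", 1:6)))
  dc <- estimate_dispersions(xc, rep(c("a", "b"), each = 3))
  expect_true(all(dc$raw_dispersion == 0))
  expect_true(all(dc$final_dispersion > 0))
})

test_that("the NB Wald test recovers a planted fold change and respects symmetry", {
  set.seed(23)
  n_sp <- 200
  mu <- exp(rnorm(n_sp, log(300), 1))
  x <- t(vapply(mu, function(m) rnbinom(6, mu = m, size = 1 / 0.05), numeric(6)))
  rownames(x) <- sprintf("miR-sim-%03d", seq_len(n_sp))
  colnames(x) <- sprintf("s%d", 1:6)
  # plant a 4-fold change in species 1 for samples 4:6
  x[1, 4:6] <- rnbinom(3, mu = mu[1] * 4, size = 1 / 0.05)
  m <- mk_counts(x)
  grp <- rep(c("control", "EtOH"), each = 3)
  de <- nb_wald_test(m, grp, baseline = "control")
  expect_gt(de$log2fc[1], 1.2)
  expect_lt(de$log2fc[1], 2.8)
  expect_lt(de$p_value[1], 0.05)
  expect_true(de$candidate[1])

  # swapping the baseline flips the sign of the fold change only
  de2 <- nb_wald_test(m, grp, baseline = "EtOH")
  expect_equal(de$log2fc, -de2$log2fc, tolerance = 1e-6)
  expect_equal(de$p_value, de2$p_value, tolerance = 1e-6)

  # a species constant across all samples has log2fc 0
  xc <- x; xc[2, ] <- 123
  dec <- nb_wald_test(mk_counts(xc), grp, sf = structure(rep(1, 6), names = colnames(x)))
  expect_equal(dec$log2fc[2], 0, tolerance = 1e-8)

  # BH q-values are monotone nondecreasing in p within the tested class
  ord <- order(de$p_value)
  expect_true(all(diff(de$q_value[ord]) >= -1e-12))
})

test_that("fold-change estimates agree with DESeq2 on shared input", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  n_sp <- 150
  mu <- exp(rnorm(n_sp, log(200), 1))
  lfc <- sample(c(0, 0, 0, 1, -1), n_sp, replace = TRUE)
  grp <- rep(c("control", "EtOH"), each = 4)
  x <- t(vapply(seq_len(n_sp), function(i) {
    m <- mu[i] * 2^(lfc[i] * (grp == "EtOH"))
    rnbinom(8, mu = m, size = 1 / 0.05)
  }, numeric(8)))
  rownames(x) <- sprintf("miR-sim-%03d", seq_len(n_sp))
  colnames(x) <- sprintf("s%d", 1:8)
  de <- nb_wald_test(mk_counts(x), grp, baseline = "control")

  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = x,
    colData = S4Vectors::DataFrame(condition = factor(grp, c("control", "EtOH"))),
    design = ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(de$log2fc) & !is.na(res$log2FoldChange)
  expect_gt(cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.95)
  strong <- ok & abs(res$log2FoldChange) > 0.5 & res$padj < 0.05 & !is.na(res$padj)
  expect_true(all(sign(de$log2fc[strong]) == sign(res$log2FoldChange[strong])))
})

test_that("size factors agree with DESeq2's estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(37)
  x <- t(vapply(exp(rnorm(100, log(100), 1)),
                function(m) rnbinom(6, mu = m * c(1, 2, 0.5, 1, 1.5, 0.8),
                                    size = 20), numeric(6)))
  rownames(x) <- sprintf("sp%d", 1:100); colnames(x) <- sprintf("s%d", 1:6)
  sf <- as.numeric(size_factors_median_of_ratios(x))
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(x)
  expect_equal(sf, unname(sf_ref), tolerance = 1e-9)
})

test_that("the piRNA pipeline normalizes against miRNA counts only", {
  set.seed(41)
  n_mi <- 30; n_pi <- 60
  cj <- c(1, 2, 4, 1, 2, 4)
  base_mi <- exp(rnorm(n_mi, log(100), 0.5))
  base_pi <- exp(rnorm(n_pi, log(400), 0.5))
  # miRNA columns exactly proportional with constants c_j -> piRNA counts are
  # divided by factors proportional to c_j
  x <- rbind(
    round(outer(base_mi, cj)),
    t(vapply(base_pi, function(m)
      as.numeric(rnbinom(6, mu = m * cj, size = 1 / 0.05)), numeric(6)))
  )
  rownames(x) <- c(sprintf("miR-sim-%03d", 1:n_mi), sprintf("piR-sim-%04d", 1:n_pi))
  colnames(x) <- sprintf("s%d", 1:6)
  cls <- setNames(classify_species(rownames(x)), rownames(x))
  m <- mk_counts(x, class = cls)
  grp <- rep(c("control", "EtOH"), 3)

  sf_mi <- as.numeric(size_factors_median_of_ratios(x[cls == "miRNA", ]))
  expect_equal(sf_mi / sf_mi[1], cj / cj[1], tolerance = 0.05)
  de <- pirna_specific_pipeline(m, grp, baseline = "control")
  expect_true(all(de$class == "piRNA"))
  expect_equal(nrow(de), n_pi)
  # no planted effect: rejections near the nominal level
  expect_lt(mean(de$p_value < 0.05, na.rm = TRUE), 0.15)

  m_no_mi <- mk_counts(x[cls == "piRNA", ], class = cls[cls == "piRNA"])
  expect_error(pirna_specific_pipeline(m_no_mi, grp), "no miRNA")
  m_no_pi <- mk_counts(x[cls == "miRNA", ], class = cls[cls == "miRNA"])
  expect_warning(res <- pirna_specific_pipeline(m_no_pi, grp), "no piRNA")
  expect_equal(nrow(res), 0)
})

test_that("the paired class-enrichment test handles exact and degenerate cases", {
  x <- rbind(matrix(5, 2, 4), matrix(5, 2, 4))
  rownames(x) <- c("miR-sim-1", "miR-sim-2", "piR-sim-1", "piR-sim-2")
  colnames(x) <- sprintf("s%d", 1:4)
  cls <- setNames(classify_species(rownames(x)), rownames(x))
  m <- mk_counts(x, class = cls)
  r <- class_enrichment_test(m)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  # constant nonzero differences: p below machine precision, with a warning
  x2 <- x; x2[3:4, ] <- x2[3:4, ] + 1.5
  m2 <- mk_counts(x2, class = cls)
  expect_warning(r2 <- class_enrichment_test(m2), "zero variance")
  expect_lt(r2$p_value, 1e-300)
  expect_equal(r2$mean_difference, 3)

  # richness mode counts detected species
  x3 <- x; x3["piR-sim-2", ] <- 0
  m3 <- mk_counts(x3, class = cls)
  expect_warning(r3 <- class_enrichment_test(m3, mode = "richness"),
                 "zero variance")
  expect_equal(r3$mean_difference, -1)

  expect_error(class_enrichment_test(mk_counts(x[, 1, drop = FALSE], class = cls)),
               ">= 2 samples")
})

test_that("the default synthetic design yields strong piRNA enrichment", {
  w <- make_small_world(seed = 47, depth = 30000L, n_mirna = 20, n_pirna = 80,
                        n_samples_per_group = 3L)
  sim <- simulate_counts(w$design, w$ann, w$spike, seed = 47)
  cls <- setNames(classify_species(rownames(sim$counts)), rownames(sim$counts))
  m <- exomir:::new_count_matrix(
    sim$counts, cls,
    setNames(colSums(sim$counts), colnames(sim$counts)),
    setNames(colSums(sim$spike_counts), colnames(sim$counts)))
  mn <- spikein_normalize(m)
  r <- class_enrichment_test(mn)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$mean_difference, 0)
  expect_gt(r$conf_int[1], 0)
})
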