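# Independent oracles and shared fixtures, built in code at test time.

suppressPackageStartupMessages({
  library(data.table)
  library(Biostrings)
})

# Brute-force placement oracle: all end-to-end placements of `read` with at
# most v mismatches, via Biostrings mismatch scanning (independent of the
# package's seeded index).
oracle_align <- function(read, genome_chr, v) {
  out <- list()
  pat <- DNAString(read)
  L <- nchar(read)
  for (ch in names(genome_chr)) {
    subj <- DNAString(genome_chr[[ch]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else reverseComplement(pat)
      m <- matchPattern(p, subj, max.mismatch = v, with.indels = FALSE)
      if (length(m) == 0) next
      st <- start(m)
      mm <- vapply(st, function(s)
        neditStartingAt(p, subj, starting.at = s, with.indels = FALSE), 1L)
      out[[length(out) + 1]] <- data.table(
        chrom = ch, start = st - 1L, end = st - 1L + L, strand = strand,
        mismatches = as.integer(mm)
      )
    }
  }
  if (!length(out)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  rbindlist(out)[order(chrom, start, strand)]
}

# Best-stratum filter for the oracle, mirroring the reporting contract.
oracle_best_strata <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits[mismatches == min(mismatches)][order(chrom, start, strand)]
}

# Exhaustive (placement x annotation) double-loop counting oracle with the
# same window and tie rules, written as plain loops.
oracle_count <- function(records, annotations, w = assignment_windows()) {
  species <- unique(annotations$species_id)
  counts <- setNames(numeric(length(species)), species)
  rec <- as.data.frame(records)
  ann <- as.data.frame(annotations)
  for (i in seq_len(nrow(rec))) {
    match_sp <- character(); match_dist <- numeric()
    for (j in seq_len(nrow(ann))) {
      if (rec$chrom[i] != ann$chrom[j] || rec$strand[i] != ann$strand[j]) next
      if (ann$strand[j] == "+") {
        d5 <- rec$start[i] - ann$start[j]
        d3 <- rec$end[i] - ann$end[j]
      } else {
        d5 <- ann$end[j] - rec$end[i]
        d3 <- ann$start[j] - rec$start[i]
      }
      if (d5 >= w$start_lo && d5 <= w$start_hi &&
          d3 >= w$end_lo && d3 <= w$end_hi) {
        match_sp <- c(match_sp, ann$species_id[j])
        match_dist <- c(match_dist, abs(d5) + abs(d3))
      }
    }
    if (!length(match_sp)) next
    best <- match_dist == min(match_dist)
    win <- match_sp[best]
    for (sp in win)
      counts[sp] <- counts[sp] + 1 / (rec$n_placements[i] * length(win))
  }
  counts
}

# Exhaustive-enumeration average-linkage (UPGMA) oracle on a distance
# matrix; returns merge heights and leaf partitions at each step.
oracle_upgma <- function(d_mat) {
  n <- nrow(d_mat)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  d <- matrix(NA_real_, n + (n - 1), n + (n - 1))
  d[1:n, 1:n] <- d_mat
  heights <- numeric(n - 1)
  merges <- list()
  nxt <- n
  sizes <- c(rep(1, n), rep(0, n - 1))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bh <- Inf
    ids <- which(active[seq_len(nxt)])
    for (a in ids) for (b in ids) if (a < b && d[a, b] < bh) {
      bh <- d[a, b]; best <- c(a, b)
    }
    nxt <- nxt + 1
    heights[step] <- bh
    merges[[step]] <- sort(unlist(clusters[best]))
    clusters[[nxt]] <- merges[[step]]
    sizes[nxt] <- sizes[best[1]] + sizes[best[2]]
    for (o in ids) {
      if (o %in% best) next
      d[nxt, o] <- d[o, nxt] <-
        (d[o, best[1]] * sizes[best[1]] + d[o, best[2]] * sizes[best[2]]) /
        sizes[nxt]
    }
    active[best] <- FALSE
    active[nxt] <- TRUE
  }
  list(heights = heights, merges = merges)
}

# Semi-global 3' adapter oracle: enumerate every cut point, admit matches
# with errors/overlap <= rate and overlap >= min_overlap, pick minimal
# errors then the longest overlap (earliest cut).
oracle_adapter_cut <- function(seq, adapter, rate = 0.1, min_overlap = 3) {
  L <- nchar(seq); alen <- nchar(adapter)
  best_err <- Inf; best_cut <- L
  for (j in seq_len(max(L - min_overlap + 1, 0))) {   # 1-based cut candidates
    overlap <- min(alen, L - j + 1)
    if (overlap < min_overlap) next
    sfrag <- substr(seq, j, j + overlap - 1)
    afrag <- substr(adapter, 1, overlap)
    err <- sum(strsplit(sfrag, "")[[1]] != strsplit(afrag, "")[[1]])
    if (err / overlap <= rate + 1e-12 && err < best_err) {
      best_err <- err; best_cut <- j - 1
    }
  }
  best_cut
}

# Small shared simulated dataset (module scale): toy genome, annotations,
# spike-ins, and one low-depth design.
make_small_world <- function(seed = 42L, depth = 5000L, n_mirna = 12L,
                             n_pirna = 30L, error_rate = 0,
                             jitter = DEFAULT_JITTER_POINT, adapter = "AGATCGGAAGAGC",
                             n_samples_per_group = 2L, dispersion = 0.05) {
  design <- simulation_design(
    n_samples_per_group = n_samples_per_group, n_mirna = n_mirna,
    n_pirna = n_pirna, depth_per_sample = depth, error_rate = error_rate,
    jitter_probs = jitter, adapter_seq = adapter, dispersion = dispersion,
    n_planted = 4L, seed = seed
  )
  genome <- generate_genome(seed, chrom_lengths = c(20000L, 12000L),
                            n_repeat_families = 3, repeat_copies = 4)
  ann <- plant_annotations(genome, design, seed = seed)
  spike <- generate_spikeins(genome, seed = seed)
  list(design = design, genome = genome, ann = ann, spike = spike)
}

DEFAULT_JITTER_POINT <- c("0" = 1)

# write a UCSC chain file from block descriptions
write_chain <- function(path, tName, tSize, tStart, tEnd, qName, qSize,
                        qStrand, qStart, qEnd, blocks) {
  lines <- sprintf("chain 1000 %s %d + %d %d %s %d %s %d %d 1",
                   tName, tSize, tStart, tEnd, qName, qSize, qStrand, qStart, qEnd)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    lines <- c(lines, if (length(b) == 1) sprintf("%d", b[1])
               else sprintf("%d\t%d\t%d", b[1], b[2], b[3]))
  }
  writeLines(c(lines, ""), path)
  path
}

annotation_sequences <- function(genome, ann) {
  chrom_chr <- setNames(as.character(genome$seq), names(genome$seq))
  s <- substring(chrom_chr[ann$chrom], ann$start + 1L, ann$end)
  neg <- ann$strand == "-"
  if (any(neg))
    s[neg] <- as.character(reverseComplement(DNAStringSet(s[neg])))
  setNames(s, ann$species_id)
}

random_case_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
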