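# Synthetic small-RNA library generator. Emulates the statistical structure
# the downstream analysis assumes: a miRNA class (~20-24 nt) and a numerically
# dominant piRNA class (26-31 nt), multi-mapping caused by repeated genomic
# cassettes, 5'/3' boundary jitter around annotated ends, 3' adapter
# read-through, spike-in reads mixed at a fixed mass fraction, negative-
# binomial species abundances with planted condition fold changes, and a
# batch ("experiment") effect stronger than the treatment effect.

DEFAULT_JITTER <- c(
  "-4" = 0.01, "-3" = 0.04, "-2" = 0.05, "-1" = 0.10, "0" = 0.60,
  "1" = 0.10, "2" = 0.05, "3" = 0.04, "4" = 0.01
)

#' Simulation design for synthetic small-RNA libraries
#'
#' Captures the study layout (two conditions, two collection timepoints, two
#' experimental batches) and the generative parameters of the read simulator.
#'
#' @param n_samples_per_group samples per condition within each timepoint
#'   (split round-robin across batches); at least 2.
#' @param groups condition labels; the second label is the treated group that
#'   receives the planted fold changes.
#' @param batches batch ("experiment") labels.
#' @param timepoints collection timepoint labels.
#' @param n_mirna,n_pirna number of miRNA / piRNA species to plant. The
#'   defaults (150 and 600) mirror, at desk scale, a library in which several
#'   hundred miRNAs are detected and piRNA species are several-fold more
#'   numerous; the planted treatment effects then touch well under a tenth of
#'   the miRNA class, keeping the treatment signal subordinate to the batch
#'   effect as observed in these libraries.
#' @param planted_fc named numeric of log2 fold changes (treated vs control)
#'   keyed by species id, or `NULL` to plant `n_planted` miRNA effects of
#'   `|log2FC| = planted_lfc` (half up, half down) at simulation time.
#' @param n_planted,planted_lfc used when `planted_fc` is `NULL`.
#' @param dispersion negative-binomial dispersion of species abundances.
#' @param depth_per_sample reads emitted per library (exactly).
#' @param spikein_mass_fraction expected fraction of reads that are spike-in
#'   (default 1/16, i.e. a 15:1 sample-to-spike-in mixing ratio).
#' @param jitter_probs named numeric distribution over 5'/3' end offsets
#'   (names are integer offsets); must sum to 1.
#' @param error_rate per-base substitution error probability.
#' @param adapter_seq 3' adapter sequence appended to every insert.
#' @param read_length instrument read length before trimming.
#' @param batch_effect_sd SD of the per-(species, batch) Gaussian shift on the
#'   log2 mean abundance.
#' @param class_mass relative abundance mass of each genomic class; piRNA mass
#'   exceeding miRNA mass reproduces the class dominance seen in amniotic
#'   fluid libraries.
#' @param seed default RNG seed for generators that are not given one.
#' @return object of class `exomir_design` (a validated list).
#' @export
simulation_design <- function(n_samples_per_group = 3,
                              groups = c("control", "EtOH"),
                              batches = c("Exp1", "Exp2"),
                              timepoints = c("E16", "E19"),
                              n_mirna = 150,
                              n_pirna = 600,
                              planted_fc = NULL,
                              n_planted = 12,
                              planted_lfc = 2,
                              dispersion = 0.05,
                              depth_per_sample = 200000L,
                              spikein_mass_fraction = 1 / 16,
                              jitter_probs = DEFAULT_JITTER,
                              error_rate = 0.001,
                              adapter_seq = "AGATCGGAAGAGC",
                              read_length = 50L,
                              batch_effect_sd = 0.5,
                              class_mass = c(miRNA = 0.25, piRNA = 0.75),
                              seed = 1L) {
  d <- list(
    n_samples_per_group = as.integer(n_samples_per_group), groups = groups,
    batches = batches, timepoints = timepoints,
    n_mirna = as.integer(n_mirna), n_pirna = as.integer(n_pirna),
    planted_fc = planted_fc, n_planted = as.integer(n_planted),
    planted_lfc = planted_lfc, dispersion = dispersion,
    depth_per_sample = as.integer(depth_per_sample),
    spikein_mass_fraction = spikein_mass_fraction,
    jitter_probs = jitter_probs, error_rate = error_rate,
    adapter_seq = toupper(adapter_seq), read_length = as.integer(read_length),
    batch_effect_sd = batch_effect_sd, class_mass = class_mass,
    seed = as.integer(seed)
  )
  class(d) <- "exomir_design"
  errs <- validate_design(d)
  if (length(errs)) .exomir_stop("invalid design: %s", paste(errs, collapse = "; "))
  d
}

validate_design <- function(d) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(d$n_samples_per_group >= 2, "n_samples_per_group must be >= 2")
  chk(d$depth_per_sample > 0, "depth_per_sample must be > 0")
  chk(abs(sum(d$jitter_probs) - 1) < 1e-9, "jitter_probs must sum to 1")
  chk(all(d$jitter_probs >= 0), "jitter_probs must be nonnegative")
  chk(d$spikein_mass_fraction > 0 && d$spikein_mass_fraction < 1,
      "spikein_mass_fraction must be in (0,1)")
  chk(d$dispersion >= 0, "dispersion must be nonnegative")
  chk(d$error_rate >= 0 && d$error_rate < 1, "error_rate must be in [0,1)")
  chk(d$batch_effect_sd >= 0, "batch_effect_sd must be nonnegative")
  chk(length(d$groups) == 2, "exactly two condition groups are supported")
  chk(grepl("^[ACGT]*$", d$adapter_seq), "adapter_seq must be an ACGT string")
  errs
}

#' Sample sheet implied by a simulation design
#'
#' One row per library: `n_samples_per_group` samples per condition within
#' each timepoint, assigned round-robin to batches.
#'
#' @param design an `exomir_design`.
#' @return `data.table` with columns `sample`, `condition`, `batch`,
#'   `timepoint`.
#' @export
design_sample_sheet <- function(design) {
  rows <- list()
  for (tp in design$timepoints) {
    for (g in design$groups) {
      for (r in seq_len(design$n_samples_per_group)) {
        b <- design$batches[((r - 1) %% length(design$batches)) + 1]
        rows[[length(rows) + 1]] <- data.table(
          sample = sprintf("%s_%s_%s_r%d", tp, g, b, r),
          condition = g, batch = b, timepoint = tp
        )
      }
    }
  }
  rbindlist(rows)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome with repeated cassettes
#'
#' Random A/C/G/T chromosomes with `n_repeat_families` distinct ~40 nt
#' cassettes each pasted at `repeat_copies` distinct non-overlapping
#' locations. The cassette copies are what later makes reads multi-map.
#'
#' @param seed RNG seed.
#' @param chrom_lengths integer vector of chromosome lengths (each >= 1000).
#' @param n_repeat_families number of distinct cassette sequences.
#' @param repeat_copies copies planted per family (>= 1).
#' @param cassette_length cassette length in nt.
#' @return object of class `exomir_genome`: list with `seq` (a
#'   `DNAStringSet`) and `cassettes` (`data.table` of placements, 0-based
#'   half-open).
#' @export
generate_genome <- function(seed, chrom_lengths, n_repeat_families = 4,
                            repeat_copies = 4, cassette_length = 40L) {
  stopifnot(all(chrom_lengths >= 1000), repeat_copies >= 1)
  set.seed(seed)
  n_cass <- n_repeat_families * repeat_copies
  if (n_cass * (cassette_length + 2) > sum(chrom_lengths) / 2)
    .exomir_stop("genome too short to place %d cassettes without overlap", n_cass)
  chroms <- setNames(
    vapply(chrom_lengths, random_dna, character(1)),
    sprintf("chr%d", seq_along(chrom_lengths))
  )
  fam_seq <- vapply(seq_len(n_repeat_families), function(i) random_dna(cassette_length),
                    character(1))
  # place copies by rejection sampling against previously used intervals
  used <- new.env(parent = emptyenv())  # per-chrom start/end vectors
  clashes <- function(key, s, e, gap) {
    iv <- get0(key, envir = used)
    !is.null(iv) && any(iv$start < e + gap & iv$end > s - gap)
  }
  occupy <- function(key, s, e) {
    iv <- get0(key, envir = used) %||% list(start = integer(), end = integer())
    assign(key, list(start = c(iv$start, s), end = c(iv$end, e)), envir = used)
  }
  placements <- list()
  clens <- setNames(as.integer(chrom_lengths), names(chroms))
  for (f in seq_len(n_repeat_families)) {
    for (cp in seq_len(repeat_copies)) {
      placed <- FALSE
      for (try in 1:2000) {
        ch <- sample(names(chroms), 1, prob = clens / sum(clens))
        s <- sample.int(clens[[ch]] - cassette_length - 20L, 1) + 10L  # 0-based
        e <- s + cassette_length
        if (!clashes(ch, s, e, 2L)) {
          occupy(ch, s, e)
          placements[[length(placements) + 1]] <- data.table(
            family = sprintf("cassette%d", f), copy = cp,
            chrom = ch, start = s, end = e
          )
          substr(chroms[[ch]], s + 1L, e) <- fam_seq[f]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        .exomir_stop("could not place cassette family %d copy %d without overlap", f, cp)
    }
  }
  g <- list(
    seq = Biostrings::DNAStringSet(chroms),
    cassettes = if (length(placements)) rbindlist(placements) else
      data.table(family = character(), copy = integer(), chrom = character(),
                 start = integer(), end = integer()),
    family_seq = setNames(fam_seq, sprintf("cassette%d", seq_len(n_repeat_families)))
  )
  class(g) <- "exomir_genome"
  g
}

#' Plant mature small-RNA annotations on a toy genome
#'
#' Plants `n_mirna` loci of length 20-24 nt and `n_pirna` loci of 26-31 nt on
#' both strands, non-overlapping on the same strand. A fraction of species is
#' placed inside repeat cassettes; those species get one BED record per
#' cassette copy (a multi-locus, multi-mapping species).
#'
#' @param genome an `exomir_genome`.
#' @param design an `exomir_design` (uses `n_mirna`, `n_pirna`, `seed`).
#' @param cassette_fraction fraction of species planted inside cassettes.
#' @param seed RNG seed (defaults to `design$seed`).
#' @return annotation `data.table` (`species_id`, `class`, `chrom`, `start`,
#'   `end`, `strand`), 0-based half-open.
#' @export
plant_annotations <- function(genome, design, cassette_fraction = 0.2,
                              seed = design$seed) {
  stopifnot(inherits(genome, "exomir_genome"))
  set.seed(seed + 1L)
  n_mi <- design$n_mirna; n_pi <- design$n_pirna
  if (n_mi + n_pi == 0) {
    return(data.table(species_id = character(), class = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  spec <- data.table(
    species_id = c(sprintf("miR-sim-%03d", seq_len(n_mi)),
                   sprintf("piR-sim-%04d", seq_len(n_pi))),
    class = rep(c("miRNA", "piRNA"), c(n_mi, n_pi)),
    len = c(if (n_mi) sample(20:24, n_mi, replace = TRUE) else integer(),
            if (n_pi) sample(26:31, n_pi, replace = TRUE) else integer()),
    strand = sample(c("+", "-"), n_mi + n_pi, replace = TRUE)
  )
  cass <- genome$cassettes
  fams <- unique(cass$family)
  margin <- 4L  # keeps max jitter inside the cassette so every copy maps
  # at most one species per family x strand fits inside a 40 nt cassette with
  # jitter margins, so cap the cassette-planted set at that capacity
  n_in_cass <- if (length(fams)) {
    min(round(cassette_fraction * nrow(spec)), 2L * length(fams))
  } else 0L
  in_cass <- rep(FALSE, nrow(spec))
  if (n_in_cass > 0) in_cass[sample.int(nrow(spec), n_in_cass)] <- TRUE
  cass_by_family <- split(cass, cass$family)
  fam_width <- vapply(cass_by_family, function(cc) cc$end[1] - cc$start[1], 1L)

  clens <- setNames(Biostrings::width(genome$seq), names(genome$seq))
  # occupied intervals keyed by chrom x strand; cassette regions blocked for
  # both strands so random (non-cassette) species stay unique in the genome
  used <- new.env(parent = emptyenv())
  clashes <- function(key, s, e, gap) {
    iv <- get0(key, envir = used)
    !is.null(iv) && any(iv$start < e + gap & iv$end > s - gap)
  }
  occupy <- function(key, s, e) {
    iv <- get0(key, envir = used) %||% list(start = integer(), end = integer())
    assign(key, list(start = c(iv$start, s), end = c(iv$end, e)), envir = used)
  }
  for (i in seq_len(nrow(cass))) {
    occupy(paste0(cass$chrom[i], "+"), cass$start[i], cass$end[i])
    occupy(paste0(cass$chrom[i], "-"), cass$start[i], cass$end[i])
  }
  # per-family relative occupancy for cassette-planted species
  fam_used <- lapply(fams, function(f) data.table(start = integer(), end = integer(),
                                                  strand = character()))
  names(fam_used) <- fams
  out <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    L <- spec$len[i]; st <- spec$strand[i]
    if (in_cass[i]) {
      placed <- FALSE
      for (try in 1:100) {
        f <- sample(fams, 1)
        cw <- fam_width[[f]]
        if (cw - 2L * margin < L) next
        rel <- sample.int(cw - 2L * margin - L + 1L, 1) - 1L + margin
        fu <- fam_used[[f]]
        if (any(fu$strand == st & fu$start < rel + L & fu$end > rel)) next
        fam_used[[f]] <- rbind(fu, data.table(start = rel, end = rel + L, strand = st))
        copies <- cass_by_family[[f]]
        out[[i]] <- data.table(
          species_id = spec$species_id[i], class = spec$class[i],
          chrom = copies$chrom, start = copies$start + rel,
          end = copies$start + rel + L, strand = st
        )
        placed <- TRUE
        break
      }
      if (!placed) in_cass[i] <- FALSE  # fall through to a unique placement
    }
    if (!in_cass[i]) {
      placed <- FALSE
      for (try in 1:2000) {
        ch <- sample(names(clens), 1, prob = clens / sum(clens))
        s <- sample.int(clens[[ch]] - L - 20L, 1) + 10L
        e <- s + L
        if (!clashes(paste0(ch, st), s, e, 5L)) {
          occupy(paste0(ch, st), s, e)
          out[[i]] <- data.table(species_id = spec$species_id[i],
                                 class = spec$class[i], chrom = ch,
                                 start = s, end = e, strand = st)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        .exomir_stop("could not place species %s without same-strand overlap",
                     spec$species_id[i])
    }
  }
  ann <- rbindlist(out)
  validate_annotations(ann)
  ann
}

#' Generate synthetic spike-in sequences
#'
#' Random 21-23 nt sequences verified to have no exact match in the genome on
#' either strand (commercial spike-in compositions are proprietary; these are
#' synthetic stand-ins).
#'
#' @param genome an `exomir_genome`.
#' @param n number of spike-in species.
#' @param seed RNG seed.
#' @return named character vector of sequences (`spike-01`, ...).
#' @export
generate_spikeins <- function(genome, n = 8, seed = 1L) {
  set.seed(seed + 2L)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- random_dna(sample(21:23, 1))
      p <- Biostrings::DNAString(s)
      hits <- sum(Biostrings::vcountPattern(p, genome$seq)) +
        sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), genome$seq))
      if (hits == 0) { out[i] <- s; break }
    }
  }
  setNames(out, sprintf("spike-%02d", seq_len(n)))
}

# Resolve the planted fold-change map for a design: user-provided, or
# n_planted miRNA species at +/- planted_lfc (half up, half down).
resolve_planted_fc <- function(design, annotations) {
  if (!is.null(design$planted_fc)) {
    unknown <- setdiff(names(design$planted_fc), annotations$species_id)
    if (length(unknown))
      .exomir_stop("planted_fc references unknown species: %s",
                   paste(unknown, collapse = ", "))
    return(design$planted_fc)
  }
  mi <- unique(annotations[class == "miRNA", species_id])
  k <- min(design$n_planted, length(mi))
  if (k == 0) return(setNames(numeric(0), character(0)))
  ids <- mi[seq_len(k)]
  setNames(rep(c(design$planted_lfc, -design$planted_lfc), length.out = k), ids)
}

#' Simulate species-level counts for every library in a design
#'
#' The count layer of the generator (reads are built on top of it by
#' [simulate_libraries()]). Species abundances follow a gamma-Poisson
#' (negative binomial) model: per-sample gamma weights with the design
#' dispersion around class-structured log-normal base means, a per-(species,
#' batch) Gaussian log2 shift, and the planted treatment log2 fold changes.
#' The spike-in read total is Binomial(depth, spikein_mass_fraction) and the
#' remaining reads are multinomial over species weights, so each library
#' totals exactly `depth_per_sample` reads.
#'
#' @param design an `exomir_design`.
#' @param annotations annotation table (defines the species universe).
#' @param spikeins named spike-in sequences.
#' @param seed RNG seed (defaults to `design$seed`).
#' @return list: `counts` (species x sample integer matrix),
#'   `spike_counts` (spike x sample), `sample_sheet`, `planted_fc`,
#'   `base_abundance`, `batch_shift` (species x batch log2 shifts).
#' @export
simulate_counts <- function(design, annotations, spikeins = character(0),
                            seed = design$seed) {
  set.seed(seed + 3L)
  ss <- design_sample_sheet(design)
  species <- unique(annotations[, .(species_id, class)])
  ns <- nrow(species)
  if (ns == 0) .exomir_stop("annotations are empty")
  planted <- resolve_planted_fc(design, annotations)

  base <- exp(rnorm(ns, 0, 1))
  mass <- design$class_mass[species$class]
  mass[is.na(mass)] <- min(design$class_mass)
  for (cl in unique(species$class)) {
    idx <- species$class == cl
    base[idx] <- base[idx] / sum(base[idx]) * mass[idx][1]
  }
  base <- base / sum(base)
  names(base) <- species$species_id

  fc <- setNames(rep(0, ns), species$species_id)
  fc[names(planted)] <- planted

  shift <- matrix(rnorm(ns * length(design$batches), 0, design$batch_effect_sd),
                  nrow = ns, dimnames = list(species$species_id, design$batches))

  treated <- design$groups[2]
  counts <- matrix(0L, ns, nrow(ss),
                   dimnames = list(species$species_id, ss$sample))
  spk <- matrix(0L, length(spikeins), nrow(ss),
                dimnames = list(names(spikeins), ss$sample))
  for (j in seq_len(nrow(ss))) {
    lmu <- log2(base) + shift[, ss$batch[j]] +
      if (ss$condition[j] == treated) fc else 0
    mu <- 2^lmu
    w <- if (design$dispersion > 0) {
      rgamma(ns, shape = 1 / design$dispersion, scale = design$dispersion * mu)
    } else mu
    if (all(w == 0)) w <- mu
    n_spike <- if (length(spikeins)) {
      rbinom(1, design$depth_per_sample, design$spikein_mass_fraction)
    } else 0L
    counts[, j] <- as.integer(rmultinom(1, design$depth_per_sample - n_spike,
                                        w / sum(w)))
    if (length(spikeins))
      spk[, j] <- as.integer(rmultinom(1, n_spike,
                                       rep(1 / length(spikeins), length(spikeins))))
  }
  list(counts = counts, spike_counts = spk, sample_sheet = ss,
       planted_fc = planted, base_abundance = base, batch_shift = shift)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw signed end offsets from the jitter distribution.
draw_jitter <- function(n, jitter_probs) {
  offs <- as.integer(names(jitter_probs))
  if (n == 0) return(integer(0))
  sample(offs, n, replace = TRUE, prob = jitter_probs)
}

#' Simulate per-sample FASTQ libraries with ground truth
#'
#' Draws species counts with [simulate_counts()], then builds each read from
#' its source locus: the mature sequence with 5'/3' end offsets drawn from
#' `jitter_probs`, the 3' adapter appended, truncation to `read_length`, and
#' per-base substitution errors at `error_rate`. Spike-in reads carry the
#' spike-in sequence plus adapter, without jitter. Every library contains
#' exactly `depth_per_sample` reads.
#'
#' @param genome an `exomir_genome`.
#' @param annotations annotation table from [plant_annotations()].
#' @param spikeins named spike-in sequences from [generate_spikeins()].
#' @param design an `exomir_design`.
#' @param outdir if non-`NULL`, writes `<sample>.fastq.gz`, a TSV truth table,
#'   truth counts and the sample sheet there.
#' @param seed RNG seed (defaults to `design$seed`).
#' @return list: `reads` (list of per-sample `data.table`s with `id`, `seq`,
#'   `qual`), `truth` (list: `counts`, `spike_counts`, `reads` per-read
#'   table, `planted_fc`, `sample_sheet`), `paths` (when `outdir` given).
#' @export
simulate_libraries <- function(genome, annotations, spikeins, design,
                               outdir = NULL, seed = design$seed) {
  stopifnot(nrow(annotations) > 0)
  sim <- simulate_counts(design, annotations, spikeins, seed = seed)
  set.seed(seed + 4L)
  ss <- sim$sample_sheet

  chrom_chr <- setNames(as.character(genome$seq), names(genome$seq))
  ann <- copy(annotations)
  loci_per_species <- ann[, .N, by = species_id]
  n_true <- setNames(loci_per_species$N, loci_per_species$species_id)
  ann_by_species <- split(seq_len(nrow(ann)), ann$species_id)

  reads_out <- list(); truth_out <- list()
  for (j in seq_len(nrow(ss))) {
    smp <- ss$sample[j]
    cnt <- sim$counts[, j]
    src <- rep(names(cnt), cnt)
    ng <- length(src)
    # pick a locus per read (uniform among a species' loci)
    li <- vapply(ann_by_species[src], function(ix)
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1)], integer(1))
    d5 <- draw_jitter(ng, design$jitter_probs)
    d3 <- draw_jitter(ng, design$jitter_probs)
    a_start <- ann$start[li]; a_end <- ann$end[li]
    a_chrom <- ann$chrom[li]; a_strand <- ann$strand[li]
    plus <- a_strand == "+"
    # 5' offset d5 and 3' offset d3 are in transcript orientation:
    # positive d5 shifts the 5' end downstream (into the annotation),
    # positive d3 extends the 3' end downstream (past the annotated end)
    g_start <- ifelse(plus, a_start + d5, a_start - d3)
    g_end <- ifelse(plus, a_end + d3, a_end - d5)
    seqs <- substring(chrom_chr[a_chrom], g_start + 1L, g_end)
    if (any(!plus)) seqs[!plus] <- revcomp_chr(seqs[!plus])

    spk_cnt <- if (nrow(sim$spike_counts)) sim$spike_counts[, j] else integer(0)
    spk_src <- rep(names(spk_cnt), spk_cnt)
    all_seq <- c(seqs, unname(spikeins[spk_src]))
    all_src <- c(src, spk_src)
    all_d5 <- c(d5, rep(0L, length(spk_src)))
    all_d3 <- c(d3, rep(0L, length(spk_src)))
    all_n <- c(unname(n_true[src]), rep(0L, length(spk_src)))

    all_seq <- substr(paste0(all_seq, design$adapter_seq), 1L, design$read_length)
    if (design$error_rate > 0) {
      nerr <- rbinom(length(all_seq), nchar(all_seq), design$error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(nchar(all_seq[i]), nerr[i])
        for (p in pos) {
          old <- substr(all_seq[i], p, p)
          substr(all_seq[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    ids <- sprintf("%s_read%07d", smp, seq_along(all_seq))
    rd <- data.table(id = ids, seq = all_seq,
                     qual = strrep("I", nchar(all_seq)))
    reads_out[[smp]] <- rd
    truth_out[[smp]] <- data.table(
      read_id = ids, sample = smp, source_id = all_src,
      class = classify_species(all_src),
      offset5 = all_d5, offset3 = all_d3, n_true_placements = all_n
    )
  }
  truth_reads <- rbindlist(truth_out)
  truth <- list(counts = sim$counts, spike_counts = sim$spike_counts,
                reads = truth_reads, planted_fc = sim$planted_fc,
                sample_sheet = ss, base_abundance = sim$base_abundance,
                batch_shift = sim$batch_shift)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fq <- setNames(file.path(outdir, paste0(ss$sample, ".fastq.gz")), ss$sample)
    for (smp in ss$sample) write_fastq(reads_out[[smp]], fq[[smp]])
    fwrite(truth_reads, file.path(outdir, "truth_reads.tsv"), sep = "\t")
    tc <- data.table(species = rownames(sim$counts))
    fwrite(cbind(tc, as.data.table(sim$counts)),
           file.path(outdir, "truth_counts.tsv"), sep = "\t")
    fwrite(ss, file.path(outdir, "sample_sheet.tsv"), sep = "\t")
    paths <- list(fastq = fq,
                  truth_reads = file.path(outdir, "truth_reads.tsv"),
                  truth_counts = file.path(outdir, "truth_counts.tsv"),
                  sample_sheet = file.path(outdir, "sample_sheet.tsv"))
  }
  list(reads = reads_out, truth = truth, sample_sheet = ss, paths = paths)
}
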