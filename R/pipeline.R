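# End-to-end orchestration: simulate (or load) libraries, trim, align,
# quantify, normalize, test, cluster, report — with a run manifest that
# records every parameter and seed.

#' Build a pipeline run configuration
#'
#' @param design an `exomir_design` (simulation block), or `NULL` when
#'   `fastq` paths plus a sample sheet are supplied.
#' @param fastq named character vector of FASTQ paths (names = samples);
#'   ignored when `design` is given.
#' @param sample_sheet sample sheet `data.table` (required with `fastq`).
#' @param genome `exomir_genome` or FASTA path (required with `fastq`).
#' @param annotations annotation table or BED path (required with `fastq`).
#' @param spikeins named spike-in sequences or FASTA path.
#' @param trim an `exomir_trim_params`.
#' @param aligner an `exomir_aligner_params`.
#' @param windows an `exomir_windows`.
#' @param p_threshold candidate p-value threshold.
#' @param candidate_on `"p"` (raw, default) or `"q"` (BH-adjusted).
#' @param batch_mode `"covariate"` to include batch additively in the DE
#'   model, `"ignore"` to omit it.
#' @param max_candidates candidate list cap.
#' @param seed master seed.
#' @return list of class `exomir_config`.
#' @export
run_config <- function(design = NULL, fastq = NULL, sample_sheet = NULL,
                       genome = NULL, annotations = NULL, spikeins = NULL,
                       trim = trim_params(), aligner = aligner_params(),
                       windows = assignment_windows(), p_threshold = 0.05,
                       candidate_on = "p", batch_mode = "covariate",
                       max_candidates = 12L, seed = 1L) {
  cfg <- list(design = design, fastq = fastq, sample_sheet = sample_sheet,
              genome = genome, annotations = annotations, spikeins = spikeins,
              trim = trim, aligner = aligner, windows = windows,
              p_threshold = p_threshold, candidate_on = candidate_on,
              batch_mode = batch_mode, max_candidates = as.integer(max_candidates),
              seed = as.integer(seed))
  class(cfg) <- "exomir_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of the nested parameter types and the existence of
#' referenced paths; all violations are returned, none raised.
#'
#' @param cfg an `exomir_config`.
#' @return character vector of violations (empty when the config is valid).
#' @export
validate_config <- function(cfg) {
  errs <- character()
  if (is.null(cfg$design) && is.null(cfg$fastq))
    errs <- c(errs, "either a simulation design or fastq inputs are required")
  if (!is.null(cfg$design)) errs <- c(errs, validate_design(cfg$design))
  if (!is.null(cfg$fastq)) {
    miss <- cfg$fastq[!file.exists(cfg$fastq)]
    if (length(miss))
      errs <- c(errs, sprintf("missing fastq path: %s", miss))
    if (is.null(cfg$sample_sheet))
      errs <- c(errs, "a sample sheet is required with fastq inputs")
    if (is.null(cfg$genome)) errs <- c(errs, "a genome is required with fastq inputs")
    if (is.null(cfg$annotations))
      errs <- c(errs, "annotations are required with fastq inputs")
    for (field in c("genome", "annotations", "spikeins")) {
      v <- cfg[[field]]
      if (is.character(v) && length(v) == 1 && !file.exists(v))
        errs <- c(errs, sprintf("missing %s path: %s", field, v))
    }
  }
  errs <- c(errs, validate_trim_params(cfg$trim))
  errs <- c(errs, validate_aligner_params(cfg$aligner))
  errs <- c(errs, validate_windows(cfg$windows))
  if (!(cfg$p_threshold > 0 && cfg$p_threshold < 1))
    errs <- c(errs, "p_threshold must be in (0,1)")
  if (!cfg$candidate_on %in% c("p", "q"))
    errs <- c(errs, "candidate_on must be 'p' or 'q'")
  if (!cfg$batch_mode %in% c("covariate", "ignore"))
    errs <- c(errs, "batch_mode must be 'covariate' or 'ignore'")
  errs
}

#' Run the pipeline end-to-end
#'
#' Stages: simulate (when a design is given) -> trim -> spike-in counting ->
#' align -> fuzzy-window quantification with 1/n multi-map weights -> merge
#' -> spike-in + size-factor normalization -> per-timepoint NB Wald DE
#' (miRNA, and piRNA with miRNA-derived size factors) -> correlation /
#' dendrogram / label association -> candidate report. All outputs and a
#' JSON manifest are written under `outdir`.
#'
#' @param cfg an `exomir_config`.
#' @param outdir run directory (created).
#' @return list with the main in-memory results (`counts`, `normalized`,
#'   `de`, `candidates`, `correlation`, `label_association`, `manifest`).
#' @export
run_pipeline <- function(cfg, outdir) {
  errs <- validate_config(cfg)
  if (length(errs))
    .exomir_stop("invalid configuration:\n- %s", paste(errs, collapse = "\n- "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("exomir")),
                   seed = cfg$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  # -- inputs: simulate or load ------------------------------------------
  truth <- NULL
  if (!is.null(cfg$design)) {
    sim <- t_stage("simulate", {
      genome <- generate_genome(cfg$seed, chrom_lengths = c(60000L, 40000L),
                                n_repeat_families = 4, repeat_copies = 4)
      ann <- plant_annotations(genome, cfg$design, seed = cfg$seed)
      spike <- generate_spikeins(genome, seed = cfg$seed)
      libs <- simulate_libraries(genome, ann, spike, cfg$design,
                                 outdir = file.path(outdir, "sim"),
                                 seed = cfg$seed)
      list(genome = genome, ann = ann, spike = spike, libs = libs)
    })
    genome <- sim$genome; ann <- sim$ann; spike <- sim$spike
    reads_by_sample <- sim$libs$reads
    ss <- sim$libs$sample_sheet
    truth <- sim$libs$truth
  } else {
    genome <- if (is.character(cfg$genome)) read_fasta(cfg$genome) else cfg$genome
    ann <- if (is.character(cfg$annotations)) read_annotations_bed(cfg$annotations)
           else cfg$annotations
    spike <- if (is.character(cfg$spikeins)) read_fasta(cfg$spikeins)
             else (cfg$spikeins %||% character(0))
    ss <- if (is.character(cfg$sample_sheet)) read_sample_sheet(cfg$sample_sheet)
          else as.data.table(cfg$sample_sheet)
    reads_by_sample <- lapply(setNames(cfg$fastq, names(cfg$fastq)), read_fastq)
  }

  # -- trim, count spike-ins, align, quantify, per sample -----------------
  idx <- t_stage("index", build_index(genome, cfg$aligner$seed_length))
  columns <- list(); spike_totals <- c(); attrition <- list()
  t_stage("quantify", {
    for (smp in ss$sample) {
      pp <- preprocess_reads(reads_by_sample[[smp]], cfg$trim)
      attrition[[smp]] <- pp$report
      sp <- count_spikeins(pp$reads, spike)
      spike_totals[smp] <- sp$total
      alns <- align_reads(pp$reads, idx, cfg$aligner)
      columns[[smp]] <- count_sample(alns, ann, cfg$windows)
    }
    NULL
  })
  m <- merge_counts(columns, ss, ann, spikein_totals = spike_totals)
  write_count_matrix(m, file.path(outdir, "counts_raw.tsv"))

  # -- normalize ----------------------------------------------------------
  mn <- t_stage("normalize", spikein_normalize(m))
  write_count_matrix(mn, file.path(outdir, "counts_spikenorm.tsv"))
  enrich <- class_enrichment_test(mn)

  # -- differential expression per timepoint and class --------------------
  de <- t_stage("diffexp", {
    out <- list()
    for (tp in unique(ss$timepoint)) {
      sel <- ss$timepoint == tp
      sub <- new_count_matrix(mn$counts[, sel, drop = FALSE], mn$class,
                              mn$total_mapped[sel], mn$spikein_counts[sel],
                              normalized = TRUE)
      grp <- ss$condition[sel]
      bt <- if (cfg$batch_mode == "covariate") ss$batch[sel] else NULL
      mi <- names(sub$class)[sub$class == "miRNA"]
      sub_mi <- new_count_matrix(sub$counts[mi, , drop = FALSE], sub$class[mi],
                                 sub$total_mapped, sub$spikein_counts,
                                 normalized = TRUE)
      de_mi <- nb_wald_test(sub_mi, grp, baseline = ss$condition[1], batch = bt,
                            alpha = cfg$p_threshold, candidate_on = cfg$candidate_on)
      de_pi <- pirna_specific_pipeline(sub, grp, baseline = ss$condition[1],
                                       batch = bt, alpha = cfg$p_threshold,
                                       candidate_on = cfg$candidate_on)
      fwrite(de_mi, file.path(outdir, sprintf("de_miRNA_%s.tsv", tp)), sep = "\t")
      fwrite(de_pi, file.path(outdir, sprintf("de_piRNA_%s.tsv", tp)), sep = "\t")
      out[[tp]] <- list(miRNA = de_mi, piRNA = de_pi)
    }
    out
  })

  # -- clustering and reporting ------------------------------------------
  cl <- t_stage("cluster", {
    cmat <- correlation_matrix(mn, class = "miRNA")
    hc <- build_dendrogram(cmat)
    write_dendrogram_newick(hc, file.path(outdir, "dendrogram.newick"))
    fwrite(as.data.table(cmat, keep.rownames = "sample"),
           file.path(outdir, "correlation_miRNA.tsv"), sep = "\t")
    assoc <- lapply(
      c(batch = "batch", treatment = "condition", timepoint = "timepoint"),
      function(col) label_association(cmat, ss[[col]], n_perm = 1000L,
                                      seed = cfg$seed)
    )
    list(cmat = cmat, hc = hc, assoc = assoc)
  })
  de_mi_all <- rbindlist(lapply(names(de), function(tp)
    cbind(timepoint = tp, de[[tp]]$miRNA)))
  candidates <- select_candidates(de_mi_all, cfg$max_candidates, cfg$p_threshold)
  fwrite(candidates, file.path(outdir, "candidates_miRNA.tsv"), sep = "\t")

  manifest$parameters <- list(
    trim = unclass(cfg$trim), aligner = unclass(cfg$aligner),
    windows = unclass(cfg$windows), p_threshold = cfg$p_threshold,
    candidate_on = cfg$candidate_on, batch_mode = cfg$batch_mode,
    design = if (!is.null(cfg$design))
      unclass(cfg$design)[setdiff(names(cfg$design), "planted_fc")] else NULL
  )
  manifest$attrition <- attrition
  manifest$class_enrichment <- list(t = enrich$t, p_value = enrich$p_value)
  manifest$label_association <- lapply(cl$assoc, function(a)
    list(score = a$score, p_value = a$p_value))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(counts = m, normalized = mn, de = de, candidates = candidates,
       correlation = cl$cmat, dendrogram = cl$hc,
       label_association = cl$assoc, class_enrichment = enrich,
       truth = truth, sample_sheet = ss, manifest = manifest)
}
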