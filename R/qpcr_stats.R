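# Relative-quantification statistics for the qPCR verification stage:
# delta-Ct against a reference small RNA (RNU1A by default), delta-delta-Ct
# fold changes, one-way ANOVA group comparisons, and standard errors.

#' Read a Ct table
#'
#' Tab-delimited with columns `sample_id`, `group`, `target_id`, `ct` and an
#' optional `replicate` column for technical replicates.
#'
#' @param path TSV path.
#' @return `data.table` of Ct rows.
#' @export
read_ct_table <- function(path) {
  ct <- fread(path, sep = "\t")
  req <- c("sample_id", "group", "target_id", "ct")
  if (!all(req %in% names(ct)))
    .exomir_stop("Ct table must have columns: %s", paste(req, collapse = ", "))
  if (any(!(ct$ct > 0))) .exomir_stop("Ct values must be positive")
  ct
}

#' Per-sample delta-Ct against the reference assay
#'
#' Technical replicates are averaged first; then
#' `dCt = Ct(target) - Ct(reference)` per sample. Samples lacking the
#' reference are excluded for all targets, with a warning. A missing target
#' Ct yields a missing dCt, never zero.
#'
#' @param ct Ct `data.table` (see [read_ct_table()]).
#' @param reference reference target id (default `"RNU1A"`).
#' @return `data.table`: `sample_id`, `group`, `target_id`, `dct`.
#' @export
delta_ct <- function(ct, reference = "RNU1A") {
  ct <- as.data.table(ct)
  avg <- ct[, .(ct = mean(ct)), by = .(sample_id, group, target_id)]
  ref <- avg[target_id == reference, .(sample_id, ref_ct = ct)]
  no_ref <- setdiff(unique(avg$sample_id), ref$sample_id)
  if (length(no_ref)) {
    warning("sample(s) without reference Ct excluded: ",
            paste(no_ref, collapse = ", "))
    avg <- avg[!sample_id %in% no_ref]
  }
  out <- merge(avg[target_id != reference], ref, by = "sample_id")
  out[, dct := ct - ref_ct]
  out[, .(sample_id, group, target_id, dct)]
}

#' Relative fold change by delta-delta-Ct
#'
#' `ddCt = mean(treated dCt) - mean(control dCt)`; fold =
#' `efficiency^-ddCt` (efficiency 2 assumes perfect doubling per cycle).
#'
#' @param dct_control,dct_treated numeric vectors of per-sample dCt values.
#' @param efficiency amplification efficiency (default 2).
#' @return list: `ddct`, `fold`.
#' @export
relative_fold <- function(dct_control, dct_treated, efficiency = 2) {
  stopifnot(length(dct_control) > 0, length(dct_treated) > 0)
  ddct <- mean(dct_treated) - mean(dct_control)
  list(ddct = ddct, fold = efficiency^(-ddct))
}

#' One-way ANOVA across groups of delta-Ct values
#'
#' Standard between/within decomposition. With exactly two groups the
#' p-value equals the two-sided equal-variance t-test p-value.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list: `group_means`, `F`, `df` (c(between, within)), `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) .exomir_stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    .exomir_stop("every group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- sprintf("group%d", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)))
  )
  tab <- anova(lm(value ~ group, data = df))
  list(group_means = vapply(groups, mean, 1),
       F = tab[["F value"]][1],
       df = c(between = tab$Df[1], within = tab$Df[2]),
       p_value = tab[["Pr(>F)"]][1])
}

#' Standard error of the mean
#' @param values numeric vector with at least 2 values.
#' @return `sd(values) / sqrt(n)`.
#' @export
standard_error <- function(values) {
  if (length(values) < 2) .exomir_stop("need >= 2 values for a standard error")
  sd(values) / sqrt(length(values))
}

#' Full qPCR verification analysis of a Ct table
#'
#' dCt per sample, fold change (treated vs control) and one-way ANOVA per
#' target.
#'
#' @param ct Ct table (`data.table` or TSV path).
#' @param reference reference target id.
#' @param control control group label (default: first group encountered).
#' @param efficiency amplification efficiency.
#' @return `data.table`: one row per target with group means, `ddct`,
#'   `fold`, `F`, `p_value` and per-group SE of dCt.
#' @export
qpcr_analysis <- function(ct, reference = "RNU1A", control = NULL,
                          efficiency = 2) {
  if (is.character(ct)) ct <- read_ct_table(ct)
  dct <- delta_ct(ct, reference)
  grps <- unique(dct$group)
  if (is.null(control)) control <- grps[1]
  treated <- setdiff(grps, control)
  rows <- lapply(unique(dct$target_id), function(tg) {
    d <- dct[target_id == tg]
    gl <- split(d$dct, d$group)
    an <- one_way_anova(gl)
    rf <- if (length(treated) == 1) {
      relative_fold(gl[[control]], gl[[treated]], efficiency)
    } else list(ddct = NA_real_, fold = NA_real_)
    data.table(target_id = tg,
               mean_dct_control = mean(gl[[control]]),
               se_dct_control = standard_error(gl[[control]]),
               ddct = rf$ddct, fold = rf$fold,
               F = an$F, p_value = an$p_value)
  })
  rbindlist(rows)
}

#' Simulate a synthetic Ct table
#'
#' Seeded generator for qPCR verification inputs: per-target baseline Ct
#' around 25 cycles, a stable reference assay near 20 cycles, planted
#' log2 expression shifts in the treated group (expression up means Ct
#' down), technical triplicates with Gaussian noise.
#'
#' @param targets character vector of target ids.
#' @param shifts named numeric log2 expression shifts (treated vs control).
#' @param n_per_group biological samples per group.
#' @param reference reference target id.
#' @param groups group labels (control first).
#' @param sd_bio,sd_tech biological / technical Ct standard deviations.
#' @param n_replicates technical replicates per (sample, target).
#' @param seed RNG seed.
#' @return Ct `data.table` suitable for [qpcr_analysis()].
#' @export
simulate_ct_table <- function(targets, shifts = NULL, n_per_group = 5,
                              reference = "RNU1A",
                              groups = c("control", "EtOH"),
                              sd_bio = 0.3, sd_tech = 0.1,
                              n_replicates = 3, seed = 1L) {
  set.seed(seed)
  if (is.null(shifts)) shifts <- setNames(rep(0, length(targets)), targets)
  base_ct <- setNames(runif(length(targets), 23, 28), targets)
  rows <- list()
  for (g in groups) {
    for (s in seq_len(n_per_group)) {
      sid <- sprintf("%s_s%d", g, s)
      ref_ct <- 20 + rnorm(1, 0, sd_bio)
      for (tg in c(reference, targets)) {
        mu <- if (tg == reference) ref_ct else {
          sh <- if (tg %in% names(shifts)) shifts[[tg]] else 0
          # expression up in the treated group lowers the Ct by the shift
          base_ct[tg] - (if (g == groups[1]) 0 else sh) +
            (ref_ct - 20) + rnorm(1, 0, sd_bio)
        }
        for (rep_i in seq_len(n_replicates)) {
          rows[[length(rows) + 1]] <- data.table(
            sample_id = sid, group = g, target_id = tg,
            replicate = rep_i, ct = mu + rnorm(1, 0, sd_tech)
          )
        }
      }
    }
  }
  rbindlist(rows)
}
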