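# Sample-correlation analysis, average-linkage dendrogram, label-association
# diagnostics, and candidate selection from DE tables.

#' Sample-sample correlation matrix on log-transformed counts
#'
#' Pearson correlation of `log2(x + pseudocount)` across species of the
#' selected class. A zero-variance sample yields `NA` entries for its pairs,
#' with a warning.
#'
#' @param m an `exomir_counts` (normalized values expected).
#' @param class species class to use (default `"miRNA"`); `NULL` for all.
#' @param pseudocount added before the log transform.
#' @return symmetric sample x sample correlation matrix.
#' @export
correlation_matrix <- function(m, class = "miRNA", pseudocount = 1) {
  stopifnot(inherits(m, "exomir_counts"))
  rows <- if (is.null(class)) rep(TRUE, nrow(m$counts)) else m$class == class
  x <- m$counts[rows, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    .exomir_stop("need >= 2 species and >= 2 samples")
  lx <- log2(x + pseudocount)
  zv <- apply(lx, 2, sd) == 0
  if (any(zv))
    warning("zero-variance sample(s): ", paste(colnames(x)[zv], collapse = ", "),
            "; their correlations are NA")
  suppressWarnings(cor(lx, method = "pearson"))
}

#' Average-linkage dendrogram on correlation distance
#'
#' Agglomerative clustering with distance `1 - r` and average linkage
#' (UPGMA). Merge heights are nondecreasing from leaves to root.
#'
#' @param c_mat complete correlation matrix from [correlation_matrix()].
#' @return an `hclust` object.
#' @export
build_dendrogram <- function(c_mat) {
  if (anyNA(c_mat)) .exomir_stop("correlation matrix has missing entries")
  hclust(as.dist(1 - c_mat), method = "average")
}

#' Write a dendrogram in newick format
#' @param hc an `hclust` from [build_dendrogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Association of a sample labelling with the correlation structure
#'
#' Score = mean within-label correlation minus mean between-label
#' correlation (off-diagonal entries). The permutation p-value shuffles the
#' labels `n_perm` times under the given seed; `n_perm = 0` skips it.
#' Labels carried by a single sample are excluded from the within-label mean
#' with a warning.
#'
#' @param c_mat sample correlation matrix.
#' @param labels character/factor per sample (batch, treatment, timepoint).
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list: `score`, `p_value` (`NA` when `n_perm = 0`), `n_perm`.
#' @export
label_association <- function(c_mat, labels, n_perm = 10000L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(c_mat))
  if (length(unique(labels)) < 2) .exomir_stop("need >= 2 distinct labels")
  singles <- names(which(table(labels) == 1))
  if (length(singles))
    warning("label(s) with a single sample excluded from the within-label mean: ",
            paste(singles, collapse = ", "))
  off <- upper.tri(c_mat)
  score_fn <- function(lab) {
    same <- outer(lab, lab, `==`)
    w <- c_mat[off & same]
    b <- c_mat[off & !same]
    if (!length(w) || !length(b)) return(NA_real_)
    mean(w) - mean(b)
  }
  obs <- score_fn(labels)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    perm <- replicate(n_perm, score_fn(sample(labels)))
    p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  list(score = obs, p_value = p, n_perm = as.integer(n_perm))
}

#' Select validation candidates from a DE table
#'
#' Species with `p_value < p_threshold`, ranked by p ascending, then
#' `|log2fc|` descending, then species id; truncated to `max_candidates`.
#' The report carries the direction (up/down in the treated group).
#'
#' @param de DE `data.table` from [nb_wald_test()].
#' @param max_candidates maximum list length (default 12).
#' @param p_threshold raw p-value threshold (default 0.05).
#' @return `data.table` of candidates with a `direction` column.
#' @export
select_candidates <- function(de, max_candidates = 12L, p_threshold = 0.05) {
  hit <- de[!is.na(p_value) & p_value < p_threshold]
  if (nrow(hit) == 0) return(hit[, direction := character(0)][])
  hit <- hit[order(p_value, -abs(log2fc), species_id)]
  hit <- head(hit, max_candidates)
  hit[, direction := ifelse(log2fc > 0, "up", "down")]
  hit[]
}
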