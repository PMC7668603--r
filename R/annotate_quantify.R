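# Assignment of alignments to mature small-RNA annotations with fuzzy end
# windows and fractional 1/n multi-map counting, plus chain-file liftover of
# annotation intervals between assemblies.

#' Fuzzy assignment windows around annotated ends
#'
#' An alignment is assigned to an annotation when its strand matches and its
#' 5' end lies within `[start_lo, start_hi]` of the annotated 5' end and its
#' 3' end within `[end_lo, end_hi]` of the annotated 3' end (strand-oriented
#' offsets, boundary-inclusive).
#'
#' @param start_lo,start_hi 5'-end offset window (defaults -3, +2).
#' @param end_lo,end_hi 3'-end offset window (defaults -2, +3).
#' @return validated list of class `exomir_windows`.
#' @export
assignment_windows <- function(start_lo = -3L, start_hi = 2L,
                               end_lo = -2L, end_hi = 3L) {
  w <- list(start_lo = as.integer(start_lo), start_hi = as.integer(start_hi),
            end_lo = as.integer(end_lo), end_hi = as.integer(end_hi))
  class(w) <- "exomir_windows"
  errs <- validate_windows(w)
  if (length(errs)) .exomir_stop("invalid windows: %s", paste(errs, collapse = "; "))
  w
}

validate_windows <- function(w) {
  errs <- character()
  if (!(w$start_lo <= 0 && 0 <= w$start_hi))
    errs <- c(errs, "start window must contain 0 (start_lo <= 0 <= start_hi)")
  if (!(w$end_lo <= 0 && 0 <= w$end_hi))
    errs <- c(errs, "end window must contain 0 (end_lo <= 0 <= end_hi)")
  errs
}

# Strand-oriented end offsets of alignments relative to annotations.
# For '+' features the 5' end is the genomic start; for '-' it is the
# genomic end. Positive 5' offset means the alignment 5' end is downstream
# (inside) of the annotated 5' end; positive 3' offset means the alignment
# extends past the annotated 3' end.
end_offsets <- function(rec_start, rec_end, rec_strand, ann_start, ann_end,
                        ann_strand) {
  plus <- ann_strand == "+"
  d5 <- ifelse(plus, rec_start - ann_start, ann_end - rec_end)
  d3 <- ifelse(plus, rec_end - ann_end, ann_start - rec_start)
  list(d5 = d5, d3 = d3)
}

#' Does an alignment fall in an annotation's fuzzy windows?
#'
#' @param rec one-row alignment record (or vectors of equal length): needs
#'   `chrom`, `start`, `end`, `strand`.
#' @param ann one-row annotation (same fields).
#' @param w an `exomir_windows`.
#' @return logical vector.
#' @export
assign_alignment <- function(rec, ann, w = assignment_windows()) {
  off <- end_offsets(rec$start, rec$end, rec$strand, ann$start, ann$end, ann$strand)
  rec$chrom == ann$chrom & rec$strand == ann$strand &
    off$d5 >= w$start_lo & off$d5 <= w$start_hi &
    off$d3 >= w$end_lo & off$d3 <= w$end_hi
}

#' Fractional species counts for one sample
#'
#' Every placement of a read that passes the fuzzy windows of an annotation
#' adds `1/n_placements` to that species. A placement whose windows admit
#' two or more annotations is resolved to the annotation with the smallest
#' `|5' offset| + |3' offset|`; exact ties split the placement's mass
#' equally (resolved pairs are counted in the return value). Placements
#' matching no annotation contribute nothing.
#'
#' @param records alignment `data.table` from [align_reads()]; each read's
#'   records must carry a consistent `n_placements`.
#' @param annotations annotation `data.table`.
#' @param w an `exomir_windows`.
#' @param per_read also return the fractional mass contributed by each read.
#' @return list: `counts` (named numeric over all species), `total_mapped`
#'   (number of distinct mapped reads), `assigned_mass` (total fractional
#'   mass assigned), `ambiguous_placements` (placements that matched more
#'   than one annotation), and with `per_read = TRUE` a `read_mass`
#'   `data.table`.
#' @export
count_sample <- function(records, annotations, w = assignment_windows(),
                         per_read = FALSE) {
  species <- unique(annotations$species_id)
  zero <- setNames(numeric(length(species)), species)
  total_mapped <- length(unique(records$read_id))
  if (nrow(records) == 0 || nrow(annotations) == 0)
    return(list(counts = zero, total_mapped = total_mapped,
                assigned_mass = 0, ambiguous_placements = 0L))

  rec <- as.data.table(records)
  rec[, placement := .I]
  ann <- as.data.table(annotations)
  ann[, ann_row := .I]

  pad <- max(abs(c(w$start_lo, w$start_hi, w$end_lo, w$end_hi)))
  rec_gr <- GenomicRanges::GRanges(rec$chrom,
                                   IRanges::IRanges(rec$start + 1L, rec$end),
                                   strand = rec$strand)
  ann_gr <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(pmax(ann$start + 1L - pad, 1L),
                                                    ann$end + pad),
                                   strand = ann$strand)
  ov <- GenomicRanges::findOverlaps(rec_gr, ann_gr, ignore.strand = FALSE)
  if (length(ov) == 0)
    return(list(counts = zero, total_mapped = total_mapped,
                assigned_mass = 0, ambiguous_placements = 0L))

  pairs <- data.table(placement = S4Vectors::queryHits(ov),
                      ann_row = S4Vectors::subjectHits(ov))
  pairs <- cbind(
    pairs,
    rec[pairs$placement, .(read_id, rs = start, re = end, strand, n_placements)],
    ann[pairs$ann_row, .(species_id, as = start, ae = end)]
  )
  off <- end_offsets(pairs$rs, pairs$re, pairs$strand, pairs$as, pairs$ae, pairs$strand)
  pairs[, `:=`(d5 = off$d5, d3 = off$d3)]
  pairs <- pairs[d5 >= w$start_lo & d5 <= w$start_hi &
                   d3 >= w$end_lo & d3 <= w$end_hi]
  if (nrow(pairs) == 0)
    return(list(counts = zero, total_mapped = total_mapped,
                assigned_mass = 0, ambiguous_placements = 0L))

  # resolve placements admitted by >= 2 annotations: smallest |d5|+|d3|,
  # ties split equally
  pairs[, dist := abs(d5) + abs(d3)]
  pairs[, n_match := .N, by = placement]
  ambiguous <- pairs[n_match > 1, uniqueN(placement)]
  pairs[, mindist := min(dist), by = placement]
  pairs <- pairs[dist == mindist]
  pairs[, n_tied := .N, by = placement]
  pairs[, weight := 1 / (n_placements * n_tied)]

  agg <- pairs[, .(count = sum(weight)), by = species_id]
  counts <- zero
  counts[agg$species_id] <- agg$count
  out <- list(counts = counts, total_mapped = total_mapped,
              assigned_mass = sum(pairs$weight),
              ambiguous_placements = as.integer(ambiguous))
  if (per_read) {
    out$read_mass <- pairs[, .(mass = sum(weight),
                               n_assigned = uniqueN(placement),
                               n_placements = n_placements[1]), by = read_id]
  }
  out
}

#' Count spike-in reads by exact sequence identity
#'
#' A trimmed read is a spike-in read when its sequence equals a spike-in
#' reference exactly (no mismatches).
#'
#' @param reads trimmed `data.table` with `seq`.
#' @param spikeins named character vector of spike-in sequences.
#' @return list: `counts` (named integer per spike-in), `total` (sum).
#' @export
count_spikeins <- function(reads, spikeins) {
  hit <- match(reads$seq, spikeins)
  tab <- tabulate(hit, nbins = length(spikeins))
  counts <- setNames(as.integer(tab), names(spikeins))
  list(counts = counts, total = sum(counts))
}

# ---- count matrix container ----------------------------------------------

new_count_matrix <- function(counts, class, total_mapped, spikein_counts,
                             normalized = FALSE) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  stopifnot(identical(names(class), rownames(counts)) || is.null(names(class)))
  m <- list(counts = counts,
            class = setNames(as.character(class), rownames(counts)),
            total_mapped = total_mapped[colnames(counts)],
            spikein_counts = spikein_counts[colnames(counts)],
            normalized = normalized)
  class(m) <- "exomir_counts"
  m
}

#' @export
print.exomir_counts <- function(x, ...) {
  cat(sprintf("exomir count matrix: %d species x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(x$normalized)) "normalized" else "raw counts"))
  cat("classes:", paste(sprintf("%s=%d", names(table(x$class)), table(x$class)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Merge per-sample count columns into a count matrix
#'
#' @param columns named list of [count_sample()] results (names = sample ids)
#'   or of plain named numeric count vectors.
#' @param sample_sheet sample sheet `data.table`; fixes the column order.
#' @param annotations annotation table supplying the species universe and
#'   classes; species absent from a sample get 0.
#' @param spikein_totals named numeric of per-sample spike-in totals
#'   (optional when `columns` carry none).
#' @param total_mapped named numeric of per-sample mapped-read totals
#'   (taken from the columns when absent).
#' @return an `exomir_counts` object with samples ordered per sample sheet.
#' @export
merge_counts <- function(columns, sample_sheet, annotations,
                         spikein_totals = NULL, total_mapped = NULL) {
  if (anyDuplicated(names(columns)))
    .exomir_stop("duplicate sample ids in columns")
  missing <- setdiff(sample_sheet$sample, names(columns))
  if (length(missing))
    .exomir_stop("samples missing from columns: %s", paste(missing, collapse = ", "))
  species <- unique(annotations[, .(species_id, class)])
  samples <- sample_sheet$sample
  counts <- matrix(0, nrow(species), length(samples),
                   dimnames = list(species$species_id, samples))
  tm <- setNames(numeric(length(samples)), samples)
  sp <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    col <- columns[[s]]
    v <- if (is.list(col)) col$counts else col
    common <- intersect(names(v), species$species_id)
    counts[common, s] <- v[common]
    tm[s] <- if (is.list(col) && !is.null(col$total_mapped)) col$total_mapped else sum(v)
  }
  if (!is.null(total_mapped)) tm[names(total_mapped)] <- total_mapped
  if (!is.null(spikein_totals)) sp[names(spikein_totals)] <- spikein_totals
  new_count_matrix(counts, setNames(species$class, species$species_id), tm, sp)
}

# ---- liftover -------------------------------------------------------------

#' Lift annotation intervals through a UCSC chain file
#'
#' Remaps intervals through the chain's gapped alignment blocks
#' (via `rtracklayer`). An interval is rejected when fewer than `min_ratio`
#' of its bases map, or when its image is split across chromosomes or
#' strands. The accepted image is the span of the mapped pieces on the
#' single destination chromosome/strand.
#'
#' @param intervals annotation-style `data.table` (`chrom`, `start`, `end`,
#'   `strand`, plus any id columns, 0-based half-open).
#' @param chain_file path to a UCSC `.chain` file (source -> destination).
#' @param min_ratio minimum fraction of bases that must map (default 0.95).
#' @return list: `lifted` (accepted intervals with remapped coordinates),
#'   `rejected` (input rows with a `reason` column).
#' @export
liftover_intervals <- function(intervals, chain_file, min_ratio = 0.95) {
  chain <- tryCatch(rtracklayer::import.chain(chain_file),
                    error = function(e) .exomir_stop("malformed chain file: %s",
                                                     conditionMessage(e)))
  iv <- as.data.table(intervals)
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end),
                               strand = iv$strand)
  mapped <- rtracklayer::liftOver(gr, chain)
  keep <- logical(nrow(iv)); rej_reason <- character(nrow(iv))
  out_chrom <- character(nrow(iv)); out_start <- integer(nrow(iv))
  out_end <- integer(nrow(iv)); out_strand <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    pieces <- mapped[[i]]
    if (length(pieces) == 0) { rej_reason[i] <- "unmapped"; next }
    chroms <- unique(as.character(GenomicRanges::seqnames(pieces)))
    strands <- unique(as.character(GenomicRanges::strand(pieces)))
    if (length(chroms) > 1 || length(strands) > 1) {
      rej_reason[i] <- "split_across_chains"; next
    }
    frac <- sum(GenomicRanges::width(pieces)) / (iv$end[i] - iv$start[i])
    if (frac < min_ratio) {
      rej_reason[i] <- sprintf("mapped_fraction_%.3f_below_%.2f", frac, min_ratio)
      next
    }
    keep[i] <- TRUE
    out_chrom[i] <- chroms
    out_start[i] <- min(GenomicRanges::start(pieces)) - 1L
    out_end[i] <- max(GenomicRanges::end(pieces))
    out_strand[i] <- strands
  }
  lifted <- iv[keep]
  if (nrow(lifted)) {
    lifted[, `:=`(chrom = out_chrom[keep], start = out_start[keep],
                  end = out_end[keep], strand = out_strand[keep])]
  }
  rejected <- iv[!keep]
  rejected[, reason := rej_reason[!keep]]
  list(lifted = lifted, rejected = rejected)
}
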