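# Read preprocessing: 3' adapter removal by semi-global suffix alignment,
# 3' quality trimming by the running-sum rule, and length filtering.

#' Trimming parameters
#'
#' @param adapter_seq 3' adapter sequence (default the small-RNA library-kit
#'   family adapter `AGATCGGAAGAGC`).
#' @param max_error_rate maximum mismatches per aligned adapter base.
#' @param min_overlap minimum adapter bases that must align at the read 3' end.
#' @param quality_cutoff Phred cutoff for 3' quality trimming.
#' @param min_length,max_length retained insert length range after trimming.
#' @return validated list of class `exomir_trim_params`.
#' @export
trim_params <- function(adapter_seq = "AGATCGGAAGAGC",
                        max_error_rate = 0.1,
                        min_overlap = 3L,
                        quality_cutoff = 20L,
                        min_length = 15L,
                        max_length = 45L) {
  p <- list(adapter_seq = toupper(adapter_seq),
            max_error_rate = max_error_rate,
            min_overlap = as.integer(min_overlap),
            quality_cutoff = as.integer(quality_cutoff),
            min_length = as.integer(min_length),
            max_length = as.integer(max_length))
  class(p) <- "exomir_trim_params"
  errs <- validate_trim_params(p)
  if (length(errs)) .exomir_stop("invalid trim params: %s", paste(errs, collapse = "; "))
  p
}

validate_trim_params <- function(p) {
  errs <- character()
  if (!(p$max_error_rate >= 0 && p$max_error_rate < 0.5))
    errs <- c(errs, "max_error_rate must be in [0, 0.5)")
  if (p$min_overlap < 1) errs <- c(errs, "min_overlap must be >= 1")
  if (p$min_length > p$max_length) errs <- c(errs, "min_length must be <= max_length")
  errs
}

#' Remove the 3' adapter from reads
#'
#' Finds the best semi-global match of the adapter against each read suffix —
#' minimal mismatch count first, then the longest overlap (earliest cut
#' point) — subject to `errors / overlap <= max_error_rate` and
#' `overlap >= min_overlap`, and removes the match and everything 3' of it.
#' Reads with no admissible match are returned unchanged. Qualities are
#' sliced identically.
#'
#' @param reads `data.table` with columns `id`, `seq`, `qual`.
#' @param params an `exomir_trim_params`.
#' @return `data.table` of the same shape with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, params = trim_params()) {
  stopifnot(nrow(reads) == 0 || all(nchar(reads$seq) >= 1))
  if (nrow(reads) == 0) return(copy(reads))
  cut <- cpp_adapter_cut(reads$seq, params$adapter_seq,
                         params$max_error_rate, params$min_overlap)
  data.table(id = reads$id,
             seq = substr(reads$seq, 1L, cut),
             qual = substr(reads$qual, 1L, cut))
}

#' Trim low-quality 3' ends
#'
#' Running-sum rule: accumulate `quality_cutoff - q` from the 3' end and cut
#' where the partial sum is largest (no cut when it never exceeds zero). A
#' zero-length result is valid and is left for the length filter to drop.
#'
#' @param reads `data.table` with `id`, `seq`, `qual` (Phred+33).
#' @param quality_cutoff Phred cutoff.
#' @return trimmed `data.table`.
#' @export
quality_trim <- function(reads, quality_cutoff = 20L) {
  if (nrow(reads) == 0) return(copy(reads))
  keep <- cpp_quality_keep(reads$qual, as.integer(quality_cutoff), 33L)
  data.table(id = reads$id,
             seq = substr(reads$seq, 1L, keep),
             qual = substr(reads$qual, 1L, keep))
}

#' Filter reads by insert length
#'
#' @param reads `data.table` with `id`, `seq`, `qual`.
#' @param min_length,max_length inclusive length bounds.
#' @return list: `reads` (passing reads) and `report` (kept/dropped counts,
#'   with dropped split into too-short and too-long).
#' @export
length_filter <- function(reads, min_length = 15L, max_length = 45L) {
  if (min_length > max_length)
    .exomir_stop("min_length (%d) exceeds max_length (%d)", min_length, max_length)
  len <- nchar(reads$seq)
  ok <- len >= min_length & len <= max_length
  list(
    reads = reads[ok],
    report = list(input = nrow(reads), kept = sum(ok),
                  dropped_short = sum(len < min_length),
                  dropped_long = sum(len > max_length))
  )
}

#' Full preprocessing of one library
#'
#' Adapter trimming, then quality trimming, then length filtering; the
#' standard small-RNA read cleanup.
#'
#' @param reads `data.table` with `id`, `seq`, `qual`, or a FASTQ path.
#' @param params an `exomir_trim_params`.
#' @param out_fastq optional path to write the surviving reads.
#' @return list: `reads`, `report` (attrition counts).
#' @export
preprocess_reads <- function(reads, params = trim_params(), out_fastq = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  r <- trim_adapter(reads, params)
  r <- quality_trim(r, params$quality_cutoff)
  lf <- length_filter(r, params$min_length, params$max_length)
  if (!is.null(out_fastq)) write_fastq(lf$reads, out_fastq)
  lf
}
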