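# Desk-scale short-read aligner: exact k-mer index + pigeonhole seeding,
# end-to-end verification with <= v substitutions, best-stratum reporting
# truncated to a report cap -- the contract of `-v 1 -k 100 --best --strata`
# style alignment. SAM read/write lets an external aligner be substituted.

#' Aligner parameters
#'
#' @param v maximum substitutions per end-to-end placement (0-3).
#' @param k report cap: at most `k` placements reported per read.
#' @param best_strata keep only the minimal-mismatch stratum.
#' @param seed_length exact k-mer seed length of the index. Completeness of
#'   the pigeonhole search is guaranteed for reads of length at least
#'   `(v + 1) * seed_length`; shorter reads (but at least `seed_length` long)
#'   fall back to exhaustive offset scanning, and reads shorter than
#'   `seed_length` are unmapped.
#' @return validated list of class `exomir_aligner_params`.
#' @export
aligner_params <- function(v = 1L, k = 100L, best_strata = TRUE, seed_length = 7L) {
  p <- list(v = as.integer(v), k = as.integer(k),
            best_strata = isTRUE(best_strata), seed_length = as.integer(seed_length))
  class(p) <- "exomir_aligner_params"
  errs <- validate_aligner_params(p)
  if (length(errs)) .exomir_stop("invalid aligner params: %s", paste(errs, collapse = "; "))
  p
}

validate_aligner_params <- function(p) {
  errs <- character()
  if (!(p$v %in% 0:3)) errs <- c(errs, "v must be in {0,1,2,3}")
  if (p$k < 1) errs <- c(errs, "k must be >= 1")
  if (p$seed_length < 4 || p$seed_length > 15)
    errs <- c(errs, "seed_length must be in [4, 15]")
  errs
}

#' Build an exact k-mer index over a genome
#'
#' @param genome an `exomir_genome`, a named character vector, a
#'   `DNAStringSet`, or a FASTA path.
#' @param seed_length k-mer length (4-15).
#' @return object of class `exomir_index` wrapping the compiled lookup
#'   structure.
#' @export
build_index <- function(genome, seed_length = 7L) {
  seqs <- genome_as_character(genome)
  ptr <- cpp_build_index(names(seqs), unname(seqs), as.integer(seed_length))
  idx <- list(ptr = ptr, chrom = names(seqs),
              chrom_len = setNames(nchar(seqs), names(seqs)),
              seed_length = as.integer(seed_length))
  class(idx) <- "exomir_index"
  idx
}

genome_as_character <- function(genome) {
  if (inherits(genome, "exomir_genome")) genome <- genome$seq
  if (is(genome, "DNAStringSet")) return(setNames(as.character(genome), names(genome)))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(read_fasta(genome))
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- sprintf("chr%d", seq_along(genome))
    return(genome)
  }
  .exomir_stop("cannot interpret genome input of class %s", class(genome)[1])
}

#' Query the index for exact occurrences of one k-mer (forward strand)
#'
#' @param index an `exomir_index`.
#' @param kmer sequence of length `seed_length`.
#' @return `data.table` with `chrom` and 0-based `start` positions.
#' @export
index_query <- function(index, kmer) {
  hit <- cpp_index_query(index$ptr, toupper(kmer))
  data.table(chrom = index$chrom[hit$chrom_idx], start = hit$start)
}

#' Align reads end-to-end with at most `v` substitutions
#'
#' Finds all placements on both strands with at most `v` mismatches; with
#' `best_strata`, only the minimal-mismatch stratum is retained. The list is
#' sorted canonically (chrom lexicographic, then start, then strand `+` before
#' `-`) and truncated to `k`; `n_placements` is the retained stratum size
#' before truncation, capped at `k`. Reads with no placement are unmapped and
#' absent from the output.
#'
#' @param reads `data.table` with `id`, `seq` (and optionally `qual`), or a
#'   character vector of sequences.
#' @param index an `exomir_index` from [build_index()].
#' @param params an `exomir_aligner_params`.
#' @return `data.table` of alignment records: `read_id`, `chrom`, `start`
#'   (0-based), `end` (half-open), `strand`, `mismatches`, `n_placements`.
#' @export
align_reads <- function(reads, index, params = aligner_params()) {
  if (is.character(reads)) reads <- data.table(id = sprintf("read%d", seq_along(reads)),
                                               seq = reads)
  hits <- cpp_align_reads(index$ptr, reads$seq, params$v, params$k,
                          params$best_strata)
  out <- data.table(
    read_id = reads$id[hits$read_idx],
    chrom = index$chrom[hits$chrom_idx],
    start = hits$start,
    end = hits$start + nchar(reads$seq[hits$read_idx]),
    strand = hits$strand,
    mismatches = hits$mismatches,
    n_placements = hits$n_placements
  )
  out
}

# ---- SAM read/write -------------------------------------------------------
# Minimal single-end SAM: one primary record per read plus secondary records
# (flag 0x100) for additional placements; the mismatch count travels in the
# standard NM tag and the placement count in NH.

#' Write alignment records as SAM
#'
#' @param records alignment `data.table` from [align_reads()] (canonically
#'   sorted per read).
#' @param path output `.sam` path.
#' @param chrom_len named vector of chromosome lengths for the header.
#' @param seqs optional named character of read sequences (by read id);
#'   written into the SEQ column when present.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path, chrom_len, seqs = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(chrom_len))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len)[i],
                       as.integer(chrom_len[i])), con)
  writeLines("@PG\tID:exomir\tPN:exomir", con)
  if (nrow(records) == 0) return(invisible(path))
  rec <- copy(as.data.table(records))
  rec[, first := !duplicated(read_id)]
  flag <- ifelse(rec$strand == "-", 16L, 0L) + ifelse(rec$first, 0L, 256L)
  seqcol <- rep("*", nrow(rec))
  if (!is.null(seqs)) {
    s <- unname(seqs[rec$read_id])
    rc <- rec$strand == "-" & !is.na(s)
    if (any(rc)) s[rc] <- revcomp_chr(s[rc])
    seqcol <- ifelse(is.na(s), "*", s)
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                   rec$read_id, flag, rec$chrom, rec$start + 1L,
                   rec$end - rec$start, seqcol, rec$mismatches, rec$n_placements)
  writeLines(lines, con)
  invisible(path)
}

#' Read alignment records from SAM
#'
#' Accepts the subset of SAM this package writes (single-end, M-only CIGAR,
#' NM and NH tags); mapped records only. Round-trips [write_alignments()]
#' record-for-record.
#'
#' @param path `.sam` path.
#' @return alignment `data.table` (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `n_placements`).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0)
    return(data.table(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), n_placements = integer()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 11)
      .exomir_stop("malformed SAM record at line %d: fewer than 11 fields", lineno)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      .exomir_stop("malformed SAM record at line %d: non-numeric FLAG/POS", lineno)
    if (bitwAnd(flag, 4L) != 0L) return(NULL)  # unmapped
    m <- regmatches(f[6], regexec("^([0-9]+)M$", f[6]))[[1]]
    if (length(m) == 0)
      .exomir_stop("unsupported CIGAR '%s' at line %d (M-only expected)", f[6], lineno)
    len <- as.integer(m[2])
    tags <- f[-(1:11)]
    nm <- sub("^NM:i:", "", grep("^NM:i:", tags, value = TRUE))
    nh <- sub("^NH:i:", "", grep("^NH:i:", tags, value = TRUE))
    data.table(read_id = f[1], chrom = f[3], start = pos - 1L,
               end = pos - 1L + len,
               strand = if (bitwAnd(flag, 16L)) "-" else "+",
               mismatches = if (length(nm)) as.integer(nm[1]) else NA_integer_,
               n_placements = if (length(nh)) as.integer(nh[1]) else NA_integer_)
  }
  hdr_n <- length(lines) - length(body)
  out <- rbindlist(Filter(Negate(is.null),
                          lapply(seq_along(fields),
                                 function(i) parse_one(fields[[i]], hdr_n + i))))
  out
}
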