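# File IO helpers: FASTQ/FASTA via Biostrings, BED6 via rtracklayer,
# count matrices as TSV + JSON sidecar. Coordinates are 0-based half-open
# everywhere inside the package (BED convention); conversions happen at the
# file boundary only.

#' Read a (gzipped) FASTQ file
#'
#' @param path FASTQ file, optionally gzip-compressed (Phred+33 qualities).
#' @return `data.table` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write reads to a (gzipped) FASTQ file
#'
#' @param reads `data.table`/data.frame with columns `id`, `seq`, `qual`.
#' @param path output path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = endsWith(path, ".gz")
  )
  invisible(path)
}

#' Write named sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write small-RNA annotations as BED6
#'
#' Columns: chrom, start (0-based), end (half-open), name = species id,
#' score 0, strand. The species class travels in the identifier prefix
#' (see [classify_species()]).
#'
#' @param ann annotation `data.table` with columns `species_id`, `class`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param path output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_annotations_bed <- function(ann, path) {
  gr <- annotations_to_granges(ann)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED6 small-RNA annotations
#'
#' @param path BED file with species ids in the name column.
#' @param class optional character vector (recycled) overriding the class
#'   inferred from the id prefix.
#' @return annotation `data.table` (`species_id`, `class`, `chrom`, `start`,
#'   `end`, `strand`) with 0-based half-open coordinates.
#' @export
read_annotations_bed <- function(path, class = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  ann <- data.table(
    species_id = gr$name,
    class = if (is.null(class)) classify_species(gr$name) else class,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  validate_annotations(ann)
  ann
}

annotations_to_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand,
    name = ann$species_id
  )
}

validate_annotations <- function(ann) {
  req <- c("species_id", "class", "chrom", "start", "end", "strand")
  if (!all(req %in% names(ann)))
    .exomir_stop("annotation table must have columns: %s", paste(req, collapse = ", "))
  if (any(ann$start >= ann$end))
    .exomir_stop("annotation intervals must satisfy start < end (0-based half-open)")
  if (!all(ann$strand %in% c("+", "-")))
    .exomir_stop("annotation strand must be '+' or '-'")
  invisible(ann)
}

#' Write a count matrix as TSV plus a JSON sidecar
#'
#' The TSV carries `species`, `class` and one column per sample; the sidecar
#' records per-sample total mapped reads and spike-in totals.
#'
#' @param m an `exomir_counts` object (see [merge_counts()]).
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "exomir_counts"))
  dt <- data.table(species = rownames(m$counts), class = m$class)
  dt <- cbind(dt, as.data.table(m$counts))
  fwrite(dt, path, sep = "\t")
  side <- list(
    samples = colnames(m$counts),
    total_mapped = as.list(m$total_mapped),
    spikein_counts = as.list(m$spikein_counts),
    normalized = isTRUE(m$normalized)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV path (expects `<path>.json` sidecar next to it).
#' @return an `exomir_counts` object.
#' @export
read_count_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- as.matrix(dt[, -(1:2)])
  rownames(counts) <- dt$species
  new_count_matrix(
    counts = counts,
    class = setNames(dt$class, dt$species),
    total_mapped = setNames(as.numeric(side$total_mapped), side$samples),
    spikein_counts = setNames(as.numeric(side$spikein_counts), side$samples),
    normalized = isTRUE(side$normalized)
  )
}

#' Read a tab-delimited sample sheet
#'
#' Expected columns: `sample`, `condition`, `batch`, `timepoint`.
#' @param path TSV path.
#' @return `data.table` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  ss <- fread(path, sep = "\t", colClasses = "character")
  req <- c("sample", "condition", "batch", "timepoint")
  if (!all(req %in% names(ss)))
    .exomir_stop("sample sheet must have columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(ss$sample))
    .exomir_stop("duplicate sample ids in sample sheet")
  ss
}
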