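#' Read and write sequence files
#'
#' Thin wrappers around Biostrings that move between files and the plain
#' data frames the rest of the package works with. Reads are represented as
#' `data.frame(id, seq, qual)` with Phred+33 quality strings; contigs as
#' `data.frame(id, seq, length, gc)`.
#'
#' @param path file path.
#' @name seq_io
NULL

#' @rdname seq_io
#' @export
read_fasta_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  contig_records(as.character(x), names(x))
}

#' @rdname seq_io
#' @param contigs contig data frame with `id` and `seq` columns.
#' @export
write_fasta_contigs <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- contigs$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname seq_io
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname seq_io
#' @param reads read data frame with `id`, `seq`, `qual` columns.
#' @export
write_fastq_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Build contig records from sequences
#'
#' GC fraction counts G and C over unambiguous (A/C/G/T) positions only;
#' ambiguous bases are excluded from both numerator and denominator.
#'
#' @param seqs character vector of DNA sequences.
#' @param ids contig identifiers.
#' @return `data.frame(id, seq, length, gc)`.
#' @export
contig_records <- function(seqs, ids = sprintf("contig_%05d", seq_along(seqs))) {
  stopifnot(length(seqs) == length(ids), !anyDuplicated(ids))
  if (any(nchar(seqs) == 0)) stop("contig sequences must be non-empty")
  data.frame(id = as.character(ids), seq = as.character(seqs),
             length = nchar(seqs), gc = gc_fraction(seqs),
             stringsAsFactors = FALSE)
}

#' GC fraction of DNA sequences
#'
#' @param seqs character vector of DNA sequences.
#' @return numeric vector; (#G + #C) / (#A + #C + #G + #T) per sequence.
#'   `NaN` when a sequence has no unambiguous base.
#' @export
gc_fraction <- function(seqs) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                     baseOnly = TRUE)
  gc <- f[, "G"] + f[, "C"]
  acgt <- gc + f[, "A"] + f[, "T"]
  unname(gc / acgt)
}

#' Reverse complement of DNA strings
#' @param seqs character vector.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Read a 12-column tabular alignment file
#'
#' The de facto standard tabular alignment export: query, subject, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, e-value, bitscore. No header line.
#'
#' @param path file path.
#' @return data frame with standard column names.
#' @export
read_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  x
}

#' @rdname read_hits
#' @param hits hit table data frame.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# round-half-up at d decimals (base round() is round-half-even); the small
# epsilon guards values like 4.45 that decimal arithmetic stores just below .5
round_half_up <- function(x, d = 0) {
  floor(x * 10^d + 0.5 + 1e-9) / 10^d
}

phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}
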