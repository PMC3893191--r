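#' Contig length filter
#'
#' Retains contigs of at least `min_len` bp. The boundary is inclusive:
#' short contigs reflect the ~200-bp RNA fragmentation of the library and
#' anything shorter is most likely truncated.
#'
#' @param contigs contig data frame (see [contig_records()]).
#' @param min_len minimum contig length (bp).
#' @return filtered contigs.
#' @export
length_filter <- function(contigs, min_len = 200) {
  contigs[contigs$length >= min_len, , drop = FALSE]
}

#' Longest open reading frame across six frames
#'
#' Translates all six frames under the standard genetic code and returns the
#' longest stop-free amino-acid stretch. A start codon is not required; ties
#' are broken by frame order (+1, +2, +3, -1, -2, -3), and within a frame by
#' first occurrence.
#'
#' @param seq a DNA string of length >= 3.
#' @return amino-acid string ("" when no frame yields a codon).
#' @export
longest_orf <- function(seq) {
  if (nchar(seq) < 3) stop("sequence must be at least 3 bp")
  best <- ""
  rc <- revcomp(seq)
  code <- genetic_code_table()
  for (fr in 1:6) {
    s <- if (fr <= 3) substr(seq, fr, nchar(seq)) else
      substr(rc, fr - 3L, nchar(rc))
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3) next
    starts <- seq.int(1L, n - 2L, by = 3L)
    aa <- code[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"                 # ambiguous codons
    aa <- paste(aa, collapse = "")
    for (frag in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(frag) > nchar(best)) best <- frag
    }
  }
  best
}

# standard genetic code as a codon -> one-letter lookup, cached per session
genetic_code_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

# alignment identity of two ORFs computed over the shorter one, in the
# CD-HIT convention: ends-free (overlap) alignment with unit match/mismatch
# scores and penalised internal gaps, so a truncated copy of the same ORF
# scores 1 while unrelated ORFs of very different lengths cannot harvest
# matches through scattered free gaps
orf_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = unit_aa_matrix(), gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

unit_aa_matrix <- function() {
  alpha <- strsplit("ARNDCQEGHILKMFPSTWYVUX*", "")[[1]]
  m <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(m) <- 1
  m
}

#' Remove redundant contigs by ORF identity
#'
#' Greedy clustering, longest contig first: a contig is a duplicate of an
#' already-retained one when the global alignment of their longest ORFs is
#' at least `aa_identity` identical over the shorter ORF; duplicates are
#' dropped and the longest representative kept. Idempotent.
#'
#' A shared-peptide prescreen (exact 20-aa word in common) limits the
#' alignments attempted on large inputs; at the 95% identity threshold a
#' duplicate pair shares such a word except in pathological mismatch
#' spacings, and ORFs shorter than 40 aa are aligned against every
#' representative unconditionally.
#'
#' @param contigs contig data frame, already length-filtered.
#' @param aa_identity identity threshold over the shorter ORF.
#' @return contigs with duplicates removed.
#' @export
dedup_contigs <- function(contigs, aa_identity = 0.95) {
  if (nrow(contigs) <= 1) return(contigs)
  ord <- order(-contigs$length, contigs$id)
  contigs <- contigs[ord, , drop = FALSE]
  orfs <- vapply(contigs$seq, longest_orf, "", USE.NAMES = FALSE)

  wsize <- 20L
  word_index <- new.env(parent = emptyenv(), hash = TRUE)
  rep_words <- function(orf, rep_i) {
    n <- nchar(orf)
    if (n < wsize) return(invisible())
    for (p in seq(1L, n - wsize + 1L)) {
      w <- substr(orf, p, p + wsize - 1L)
      word_index[[w]] <- c(word_index[[w]], rep_i)
    }
  }
  candidates <- function(orf) {
    n <- nchar(orf)
    if (n < 2L * wsize) return(NULL)       # short ORFs: align against all
    hits <- integer(0)
    for (p in seq(1L, n - wsize + 1L, by = wsize %/% 2L)) {
      w <- substr(orf, p, p + wsize - 1L)
      hits <- c(hits, word_index[[w]])
    }
    unique(hits)
  }

  kept <- logical(nrow(contigs))
  reps <- integer(0)
  for (i in seq_len(nrow(contigs))) {
    cand <- candidates(orfs[i])
    if (is.null(cand)) cand <- reps
    dup <- FALSE
    for (j in cand) {
      if (orf_identity(orfs[i], orfs[j]) >= aa_identity) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[i] <- TRUE
      reps <- c(reps, i)
      rep_words(orfs[i], i)
    }
  }
  out <- contigs[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assembly summary statistics
#'
#' N50 uses the cumulative-half convention: sort contigs longest first; N50
#' is the length at which the cumulative total first reaches half the
#' assembly size. The mean is rounded half-up to an integer.
#'
#' @param contigs non-empty contig data frame.
#' @return list with `n_contigs`, `total_bp`, `mean_bp`, `n50`, `max_bp`.
#' @export
assembly_stats <- function(contigs) {
  if (nrow(contigs) == 0) stop("assembly_stats requires a non-empty contig set")
  lens <- sort(contigs$length, decreasing = TRUE)
  total <- sum(as.numeric(lens))
  n50 <- lens[which(cumsum(as.numeric(lens)) >= total / 2)[1]]
  list(n_contigs = nrow(contigs), total_bp = total,
       mean_bp = round_half_up(total / nrow(contigs)),
       n50 = n50, max_bp = lens[1])
}
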