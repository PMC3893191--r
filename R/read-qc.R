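#' Read quality-control rules
#'
#' Native re-implementations of the read-filtering rules applied to the
#' holobiont library before assembly: 3' quality trimming at Q20, adapter
#' stripping, exact PCR-duplicate removal, and an 80-bp pair-length filter.
#' Each rule is a simple deterministic reading of the corresponding
#' published threshold. All functions are vectorised over reads and preserve
#' read identifiers; every rule is length-non-increasing.
#'
#' @name read_qc
NULL

#' Trim low-quality 3' tails
#'
#' Scans from the 3' end and removes the maximal trailing run of bases with
#' Phred quality below `q_threshold`; trimming stops at the first base (from
#' the 3' end) at or above the threshold. A fully low-quality read becomes
#' empty (not an error).
#'
#' @param seq,qual character vectors: DNA and Phred+33 quality strings of
#'   equal lengths.
#' @param q_threshold minimum Phred score to survive at the 3' end.
#' @return list with trimmed `seq` and `qual`.
#' @export
quality_trim <- function(seq, qual, q_threshold = 20) {
  stopifnot(length(seq) == length(qual), all(nchar(seq) == nchar(qual)))
  if (q_threshold > 0) {
    hi <- 32 + q_threshold            # last char code strictly below threshold
    pat <- sprintf("[\\x21-\\x%02x]+$", hi)
    qual <- sub(pat, "", qual, perl = TRUE)
    seq <- substr(seq, 1L, nchar(qual))
  }
  list(seq = seq, qual = qual)
}

#' Strip adapter contamination
#'
#' Truncates each read before the first occurrence of the full adapter; if
#' the full adapter is absent, a prefix of the adapter anchored at the 3'
#' end of the read (minimum `min_anchor` bp) is removed instead.
#'
#' @param seq,qual read sequences and qualities.
#' @param adapter adapter sequence (non-empty).
#' @param min_anchor minimum length of a 3'-anchored adapter prefix match.
#' @return list with stripped `seq` and `qual`.
#' @export
strip_adapter <- function(seq, qual, adapter, min_anchor = 8L) {
  if (is.null(adapter) || nchar(adapter) == 0) stop("adapter must be non-empty")
  hit <- regexpr(adapter, seq, fixed = TRUE)
  keep <- ifelse(hit > 0, hit - 1L, nchar(seq))
  # 3'-anchored prefix of the adapter, longest match wins
  kmax <- nchar(adapter) - 1L
  if (length(seq) > 0 && kmax >= min_anchor) {
    for (k in seq(kmax, min_anchor, by = -1L)) {
      pre <- substr(adapter, 1L, k)
      anchored <- hit <= 0 & keep == nchar(seq) & nchar(seq) >= k &
        substr(seq, nchar(seq) - k + 1L, nchar(seq)) == pre
      keep[anchored] <- nchar(seq)[anchored] - k
    }
  }
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

#' Remove PCR duplicates
#'
#' Collapses read pairs with identical sequences on both mates to the first
#' encountered representative. Idempotent; pairs identical on one mate only
#' are both kept.
#'
#' @param pairs data frame with `seq1` and `seq2` columns.
#' @return the subset of `pairs` with duplicates removed.
#' @export
remove_duplicates <- function(pairs) {
  keep <- !duplicated(paste(pairs$seq1, pairs$seq2, sep = "|"))
  pairs[keep, , drop = FALSE]
}

#' Pair-length filter
#'
#' A pair is retained only if both mates are at least `min_len` bp
#' (boundary inclusive) after trimming.
#'
#' @param pairs data frame with `seq1` and `seq2` columns.
#' @param min_len minimum mate length in bp.
#' @return filtered pairs.
#' @export
pair_length_filter <- function(pairs, min_len = 80) {
  keep <- nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len
  pairs[keep, , drop = FALSE]
}

#' Full read-QC chain
#'
#' Applies quality trimming, adapter stripping, duplicate removal and the
#' pair-length filter, in that order, to a paired read set. The chain is a
#' fixed point of itself: re-running it on its own output changes nothing.
#'
#' @param pairs data frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param q_threshold Phred trim threshold.
#' @param min_len minimum mate length (bp).
#' @param adapter adapter sequence, or `NULL` to skip adapter stripping.
#' @return list with `pairs` (the survivors) and `log` (reads dropped or
#'   altered per rule).
#' @export
qc_reads <- function(pairs, q_threshold = 20, min_len = 80, adapter = NULL) {
  n0 <- nrow(pairs)
  t1 <- quality_trim(pairs$seq1, pairs$qual1, q_threshold)
  t2 <- quality_trim(pairs$seq2, pairs$qual2, q_threshold)
  n_trimmed <- sum(nchar(t1$seq) < nchar(pairs$seq1) |
                     nchar(t2$seq) < nchar(pairs$seq2))
  pairs$seq1 <- t1$seq; pairs$qual1 <- t1$qual
  pairs$seq2 <- t2$seq; pairs$qual2 <- t2$qual
  n_adapter <- 0L
  if (!is.null(adapter)) {
    a1 <- strip_adapter(pairs$seq1, pairs$qual1, adapter)
    a2 <- strip_adapter(pairs$seq2, pairs$qual2, adapter)
    n_adapter <- sum(nchar(a1$seq) < nchar(pairs$seq1) |
                       nchar(a2$seq) < nchar(pairs$seq2))
    pairs$seq1 <- a1$seq; pairs$qual1 <- a1$qual
    pairs$seq2 <- a2$seq; pairs$qual2 <- a2$qual
  }
  deduped <- remove_duplicates(pairs)
  n_dup <- nrow(pairs) - nrow(deduped)
  out <- pair_length_filter(deduped, min_len)
  n_len <- nrow(deduped) - nrow(out)
  list(pairs = out,
       log = c(input = n0, trimmed = n_trimmed, adapter_stripped = n_adapter,
               duplicates_removed = n_dup, short_pairs_dropped = n_len,
               survivors = nrow(out)))
}
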