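#' Exclusive-hit binning of contigs against two reference genomes
#'
#' A contig "hits" a reference if any alignment row for it has an e-value at
#' or below the cutoff. Contigs hitting only the host reference are binned
#' HOST, only the symbiont reference SYMBIONT, both AMBIGUOUS (retained with
#' an explicit label rather than silently dropped), neither UNASSIGNED. The
#' four bins are mutually exclusive and exhaustive over the universe.
#'
#' @param hits_host,hits_symbiont hit tables (see [read_hits()]) with
#'   `query_id` and `evalue` columns; multiple rows per contig allowed.
#' @param all_contig_ids the contig universe.
#' @param cutoff e-value cutoff (> 0).
#' @return `data.frame(contig_id, bin)` with one row per universe id.
#' @export
assign_bins <- function(hits_host, hits_symbiont, all_contig_ids,
                        cutoff = 1e-4) {
  stopifnot(cutoff > 0, !anyDuplicated(all_contig_ids))
  hh <- unique(hits_host$query_id[hits_host$evalue <= cutoff])
  hs <- unique(hits_symbiont$query_id[hits_symbiont$evalue <= cutoff])
  foreign <- setdiff(c(hh, hs), all_contig_ids)
  if (length(foreign))
    stop("hit table contains ids outside the contig universe: ",
         paste(head(foreign, 5), collapse = ", "))
  in_h <- all_contig_ids %in% hh
  in_s <- all_contig_ids %in% hs
  bin <- ifelse(in_h & in_s, "AMBIGUOUS",
                ifelse(in_h, "HOST", ifelse(in_s, "SYMBIONT", "UNASSIGNED")))
  data.frame(contig_id = all_contig_ids,
             bin = factor(bin, levels = c("HOST", "SYMBIONT", "AMBIGUOUS",
                                          "UNASSIGNED")),
             stringsAsFactors = FALSE)
}

#' Scan e-value cutoffs for the binning step
#'
#' For each cutoff, counts contigs hitting each reference and their overlap,
#' and derives the exclusive (host-only / symbiont-only) counts. The
#' selected cutoff maximises the host-only count; ties are broken toward the
#' stricter (smaller) cutoff. Both exclusive counts are reported so the
#' symbiont-maximising choice can be audited.
#'
#' @inheritParams assign_bins
#' @param cutoffs e-value cutoffs to examine.
#' @return data frame with one row per cutoff (`cutoff`, `n_hit_host`,
#'   `n_hit_symbiont`, `n_overlap`, `n_host_only`, `n_symbiont_only`) and
#'   attribute `selected` holding the chosen cutoff.
#' @export
scan_cutoffs <- function(hits_host, hits_symbiont, all_contig_ids,
                         cutoffs = c(1e-1, 1e-2, 1e-3, 1e-4, 1e-5, 1e-10)) {
  stopifnot(length(cutoffs) > 0)
  rows <- lapply(cutoffs, function(ct) {
    hh <- unique(hits_host$query_id[hits_host$evalue <= ct])
    hs <- unique(hits_symbiont$query_id[hits_symbiont$evalue <= ct])
    ov <- length(intersect(hh, hs))
    data.frame(cutoff = ct, n_hit_host = length(hh),
               n_hit_symbiont = length(hs), n_overlap = ov,
               n_host_only = length(hh) - ov,
               n_symbiont_only = length(hs) - ov)
  })
  out <- do.call(rbind, rows)
  best <- which(out$n_host_only == max(out$n_host_only))
  sel <- min(out$cutoff[best])
  attr(out, "selected") <- sel
  out
}

#' Bin proportions over the contig universe
#'
#' @param assignments output of [assign_bins()].
#' @return named numeric vector of percentages (one decimal, half-up) per
#'   bin.
#' @export
dataset_symbiont_fraction <- function(assignments) {
  tab <- table(assignments$bin)
  round_half_up(100 * as.numeric(tab) / nrow(assignments), 1) |>
    setNames(names(tab))
}

#' Ungapped seed-and-extend nucleotide search
#'
#' A deliberately simple stand-in for an external nucleotide aligner so that
#' synthetic runs are fully self-contained: exact `word_size`-mer seeding on
#' both strands, ungapped +1/-2 extension stopped when the running score
#' drops `x_drop` below its maximum, and Karlin-Altschul e-values
#' E = K m n exp(-lambda S) with fixed K = 0.41, lambda = 0.625. It is not a
#' replacement for a real aligner on real data; externally produced
#' 12-column hit tables are ingested with [read_hits()] instead.
#'
#' @param queries named character vector of query sequences.
#' @param subject subject sequence (single string).
#' @param subject_id label for the subject column of the hit table.
#' @param word_size exact seed length (4-15).
#' @param x_drop extension termination score drop.
#' @param evalue_max report hits at or below this e-value.
#' @return hit table in 12-column layout (minus-strand hits have
#'   `sstart` > `send`; query coordinates always forward).
#' @export
native_search <- function(queries, subject, subject_id = "subject",
                          word_size = 11, x_drop = 20, evalue_max = 10) {
  if (is.null(names(queries)))
    names(queries) <- sprintf("query_%04d", seq_along(queries))
  if (any(nchar(queries) < word_size))
    stop("every query must be at least word_size long")
  hits <- .native_search_cpp(queries, subject, as.integer(word_size),
                             x_drop, 0.41, 0.625, evalue_max)
  if (nrow(hits) == 0) {
    hits$subject_id <- character(0)
  } else {
    hits$subject_id <- subject_id
  }
  hits <- hits[, c("query_id", "subject_id", "pct_identity", "aln_len",
                   "mismatches", "gap_opens", "qstart", "qend", "sstart",
                   "send", "evalue", "bitscore")]
  hits[order(hits$query_id, hits$evalue), , drop = FALSE]
}
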