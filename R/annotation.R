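#' Merge annotation evidence across sources
#'
#' Accounts for annotation coverage of the contig universe across evidence
#' sources (protein-database and genome-alignment hits, plus domain/pathway
#' term assignments). A contig counts as annotated when it has at least one
#' row in any BLAST-type or genome-alignment source (`NR`, `SWISSPROT`,
#' `HOST_GENOME`, `SYMBIONT_GENOME`); Pfam/KEGG/GO term sources are counted
#' per source but do not enter the annotated union, matching how the study
#' reports "annotated using public protein databases and genomic data".
#' Counts are independent of the order tables are supplied in.
#'
#' @param universe_ids all contig ids.
#' @param tables named list of data frames, each with a `contig_id` column;
#'   names identify the source (`NR`, `SWISSPROT`, `HOST_GENOME`,
#'   `SYMBIONT_GENOME`, `PFAM`, `KEGG`, `GO`).
#' @return list with `per_source` (source, n, pct to one decimal),
#'   `n_annotated`, `pct_annotated`, `n_unannotated`, and `annotated`
#'   (logical vector over the universe).
#' @export
merge_evidence <- function(universe_ids, tables) {
  stopifnot(!anyDuplicated(universe_ids), is.list(tables),
            !is.null(names(tables)))
  n_u <- length(universe_ids)
  blast_like <- c("NR", "SWISSPROT", "HOST_GENOME", "SYMBIONT_GENOME")
  for (src in names(tables)) {
    foreign <- setdiff(unique(tables[[src]]$contig_id), universe_ids)
    if (length(foreign))
      stop("source ", src, " has ids outside the universe: ",
           paste(head(foreign, 5), collapse = ", "))
  }
  per_source <- do.call(rbind, lapply(names(tables), function(src) {
    n <- length(unique(tables[[src]]$contig_id))
    data.frame(source = src, n = n, pct = round_half_up(100 * n / n_u, 1),
               stringsAsFactors = FALSE)
  }))
  union_ids <- unique(unlist(lapply(tables[intersect(names(tables),
                                                     blast_like)],
                                    function(t) unique(t$contig_id))))
  annotated <- universe_ids %in% union_ids
  list(per_source = per_source,
       n_annotated = sum(annotated),
       pct_annotated = round_half_up(100 * sum(annotated) / n_u, 1),
       n_unannotated = n_u - sum(annotated),
       annotated = annotated)
}

# best hit per query: smallest e-value, ties by larger bitscore then
# lexicographic subject id
best_hit_per_query <- function(hits) {
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), c("query_id", "subject_id", "evalue"),
    drop = FALSE]
}

#' Reciprocal best hits between two datasets
#'
#' (a, b) is an ortholog pair when b is a's best hit in the a-vs-b search,
#' a is b's best hit in the b-vs-a search, and both best hits have e-value
#' at or below `evalue_cutoff`. Best hits are the rows with the smallest
#' e-value (ties: larger bitscore, then lexicographic subject id). The
#' result is symmetric in the two tables.
#'
#' @param hits_ab,hits_ba 12-column hit tables for the two search
#'   directions.
#' @param evalue_cutoff significance cutoff for both directions.
#' @return `data.frame(id_a, id_b, evalue_ab, evalue_ba)`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5) {
  ba <- best_hit_per_query(hits_ab)
  bb <- best_hit_per_query(hits_ba)
  ba <- ba[ba$evalue <= evalue_cutoff, , drop = FALSE]
  bb <- bb[bb$evalue <= evalue_cutoff, , drop = FALSE]
  m <- merge(ba, bb, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_ab", "_ba"))
  out <- data.frame(id_a = m$query_id, id_b = m$subject_id,
                    evalue_ab = m$evalue_ab, evalue_ba = m$evalue_ba,
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Filter ortholog pairs by subject alignment coverage
#'
#' Coverage of the subject (b) sequence is the unioned span of its aligned
#' intervals divided by its full length; overlapping alignment segments are
#' merged before summing, so coverage never exceeds 1 and is monotone in
#' added segments. Pairs are kept when coverage is strictly greater than
#' `min_cov` ("more than 80%").
#'
#' @param pairs ortholog pairs from [reciprocal_best_hits()].
#' @param alignments hit table with `query_id`, `subject_id`, `sstart`,
#'   `send` (subject coordinates, 1-based inclusive, either orientation).
#' @param subject_lengths named vector: full length of each subject.
#' @param min_cov coverage threshold (strict).
#' @return list with `pairs` (kept rows plus a `coverage_b` column) and
#'   `n_kept`.
#' @export
coverage_filter <- function(pairs, alignments, subject_lengths,
                            min_cov = 0.80) {
  cov <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- alignments[alignments$query_id == pairs$id_a[i] &
                      alignments$subject_id == pairs$id_b[i], , drop = FALSE]
    if (nrow(a) == 0) return(0)
    sl <- unname(subject_lengths[pairs$id_b[i]])
    if (length(sl) != 1 || is.na(sl))
      stop("missing subject length for ", pairs$id_b[i])
    ir <- IRanges::reduce(IRanges::IRanges(pmin(a$sstart, a$send),
                                           pmax(a$sstart, a$send)))
    sum(IRanges::width(ir)) / sl
  }, numeric(1))
  pairs$coverage_b <- cov
  kept <- pairs[cov > min_cov, , drop = FALSE]
  list(pairs = kept, n_kept = nrow(kept))
}
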