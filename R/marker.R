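#' Recruit marker reads by exact primer match
#'
#' A read is recruited when it contains the forward primer, the reverse
#' primer, or the reverse complement of either as an exact substring (the
#' published procedure required 100% primer matches, for which exact
#' substring search is equivalent and deterministic). Idempotent.
#'
#' @param reads read data frame (`id`, `seq`, ...).
#' @param primer_fwd,primer_rev primer sequences (non-empty).
#' @return the recruited subset of `reads`.
#' @export
recruit_reads <- function(reads, primer_fwd, primer_rev) {
  stopifnot(nchar(primer_fwd) > 0, nchar(primer_rev) > 0)
  pats <- unique(c(primer_fwd, primer_rev, revcomp(primer_fwd),
                   revcomp(primer_rev)))
  hit <- Reduce(`|`, lapply(pats, function(p) grepl(p, reads$seq,
                                                    fixed = TRUE)))
  reads[hit, , drop = FALSE]
}

# longest exact suffix(a)-prefix(b) overlap with ov in [min_ov, min(na, nb)]
best_suffix_prefix <- function(a, b, min_ov) {
  na <- nchar(a); nb <- nchar(b)
  for (ov in seq(min(na, nb), min_ov, by = -1L)) {
    if (ov < min_ov) break
    if (substr(a, na - ov + 1L, na) == substr(b, 1L, ov)) return(ov)
  }
  0L
}

#' Greedy overlap-layout-consensus assembly of marker reads
#'
#' Repeatedly merges the pair of sequences with the longest exact
#' suffix-prefix overlap of at least `min_overlap` bp (both orientations
#' considered; a read wholly contained in another is absorbed) until no
#' merge is possible, then returns the longest resulting contig. Because
#' merges require exact overlaps, the per-column majority consensus equals
#' the concatenated layout. With zero sequencing error and tiling coverage
#' the result is invariant to read input order (ties are broken
#' lexicographically).
#'
#' When `extension_reads` are supplied, the assembled contig is then
#' iteratively extended with any extension read overlapping either end by
#' at least `min_overlap` bp, longest overlap first.
#'
#' @param reads recruited read data frame (`seq` column; at least one read).
#' @param min_overlap minimum exact overlap (bp).
#' @param extension_reads optional read data frame used only to extend the
#'   assembled contig.
#' @return list with `consensus`, `length`, `n_reads_used`, and
#'   `no_overlap_warning` (`TRUE` when no merge was ever possible and the
#'   longest single read is returned).
#' @export
assemble_marker <- function(reads, min_overlap = 30, extension_reads = NULL) {
  seqs <- reads$seq
  if (length(seqs) < 1) stop("assemble_marker needs at least one read")
  merged_any <- FALSE
  n_used <- length(seqs)
  repeat {
    if (length(seqs) < 2) break
    best <- list(score = 0L)
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        if (i == j) next
        for (ai in c(seqs[i], revcomp(seqs[i]))) {
          for (bj in c(seqs[j], revcomp(seqs[j]))) {
            # containment: absorb j into i
            if (nchar(bj) <= nchar(ai) && grepl(bj, ai, fixed = TRUE)) {
              cand <- list(score = nchar(bj), merged = ai, drop = c(i, j))
            } else {
              ov <- best_suffix_prefix(ai, bj, min_overlap)
              if (ov == 0L) next
              cand <- list(score = ov,
                           merged = paste0(ai, substr(bj, ov + 1L,
                                                      nchar(bj))),
                           drop = c(i, j))
            }
            cand$merged <- min(cand$merged, revcomp(cand$merged))
            if (cand$score > best$score ||
                (cand$score == best$score && !is.null(best$merged) &&
                 cand$merged < best$merged))
              best <- cand
          }
        }
      }
    }
    if (best$score == 0L) break
    merged_any <- TRUE
    seqs <- c(seqs[-best$drop], best$merged)
  }
  longest <- seqs[nchar(seqs) == max(nchar(seqs))]
  contig <- min(longest)                 # deterministic under ties

  if (!is.null(extension_reads) && nrow(extension_reads) > 0)
    contig <- extend_contig(contig, extension_reads$seq, min_overlap)

  list(consensus = contig, length = nchar(contig), n_reads_used = n_used,
       no_overlap_warning = !merged_any && length(reads$seq) > 1)
}

# iteratively extend a contig with pool reads overlapping either end by
# >= min_ov exact bp; vectorised over the pool, longest overlap first
extend_contig <- function(contig, pool, min_ov) {
  pool <- unique(pool)
  cand <- c(pool, revcomp(pool))       # both orientations, computed once
  np <- nchar(cand)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > 4L * length(cand) + 10L) break   # repeat-sequence guard
    nc <- nchar(contig)
    found <- FALSE
    for (ov in seq(min(max(np), nc), min_ov, by = -1L)) {
      # right extension: contig suffix == read prefix, read longer than ov
      right <- np > ov & substr(cand, 1L, ov) ==
        substr(contig, nc - ov + 1L, nc)
      if (any(right)) {
        r <- cand[which(right)[1]]
        contig <- paste0(contig, substr(r, ov + 1L, nchar(r)))
        found <- TRUE
        break
      }
      # left extension: read suffix == contig prefix
      left <- np > ov & substr(cand, np - ov + 1L, np) ==
        substr(contig, 1L, ov)
      if (any(left)) {
        r <- cand[which(left)[1]]
        contig <- paste0(substr(r, 1L, nchar(r) - ov), contig)
        found <- TRUE
        break
      }
    }
    if (!found) break
    # drop reads now contained in the contig
    keep <- !vapply(cand, function(p) grepl(p, contig, fixed = TRUE),
                    logical(1), USE.NAMES = FALSE)
    cand <- cand[keep]
    np <- np[keep]
    if (length(cand) == 0) break
  }
  contig
}

#' Orient an assembled marker by its forward primer
#'
#' Assembly orientation is arbitrary; this flips the consensus so that the
#' forward primer reads in the forward direction.
#'
#' @param seq assembled consensus.
#' @param primer_fwd forward primer sequence.
#' @return `seq`, reverse complemented if the primer was found on the minus
#'   strand; unchanged if the primer is absent from both strands.
#' @export
orient_by_primer <- function(seq, primer_fwd) {
  if (grepl(primer_fwd, seq, fixed = TRUE)) return(seq)
  rc <- revcomp(seq)
  if (grepl(primer_fwd, rc, fixed = TRUE)) return(rc)
  seq
}

#' Type a marker consensus against a reference panel
#'
#' Global alignment (unit match/mismatch scores, gap cost 1) of the
#' consensus against every panel entry; the best type maximises the number
#' of identical aligned bases. Ties are broken by panel order and flagged.
#'
#' @param consensus assembled marker sequence.
#' @param panel `data.frame(name, seq)` with unique names and non-empty
#'   sequences.
#' @return list with `best_type`, `identical_bp`, `aligned_bp` (alignment
#'   columns including gaps), `tie`, and the per-entry score table
#'   `scores`.
#' @export
type_marker <- function(consensus, panel) {
  stopifnot(nrow(panel) > 0, !anyDuplicated(panel$name),
            all(nchar(panel$seq) > 0))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  res <- lapply(panel$seq, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(consensus), Biostrings::DNAString(s),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    list(ident = Biostrings::nmatch(aln),
         alen = nchar(as.character(Biostrings::pattern(aln))))
  })
  ident <- vapply(res, `[[`, numeric(1), "ident")
  alen <- vapply(res, `[[`, numeric(1), "alen")
  best <- which.max(ident)
  list(best_type = panel$name[best], identical_bp = ident[best],
       aligned_bp = alen[best], tie = sum(ident == ident[best]) > 1,
       scores = data.frame(name = panel$name, identical_bp = ident,
                           aligned_bp = alen, stringsAsFactors = FALSE))
}

#' Check within-marker sequence variation
#'
#' Places each read (or its reverse complement) at its best-matching offset
#' on the consensus and tallies alleles per column; a column is a variant
#' when at least two alleles are each supported by at least two reads.
#'
#' @param reads read data frame (`seq`); typically the recruited/marker set.
#' @param consensus assembled marker sequence.
#' @return number of variant columns.
#' @export
marker_variant_check <- function(reads, consensus) {
  Lc <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1]]
  counts <- list()   # per column: named allele counts
  for (s in reads$seq) {
    lr <- nchar(s)
    if (lr > Lc) next
    best <- NULL
    for (cand in c(s, revcomp(s))) {
      cc <- strsplit(cand, "")[[1]]
      for (off in 0:(Lc - lr)) {
        m <- sum(cc == cons[(off + 1):(off + lr)])
        if (is.null(best) || m > best$m) best <- list(m = m, off = off, cc = cc)
      }
    }
    for (p in seq_len(lr)) {
      col <- best$off + p
      a <- best$cc[p]
      key <- as.character(col)
      cur <- counts[[key]]
      if (is.null(cur)) cur <- integer(0)
      cur[a] <- if (is.na(cur[a])) 1L else cur[a] + 1L
      counts[[key]] <- cur
    }
  }
  sum(vapply(counts, function(cn) sum(cn >= 2L) >= 2L, logical(1)))
}

#' Build a synthetic marker reference panel
#'
#' Panel entries are derived from the planted marker by introducing fixed
#' numbers of substitutions, so that the expected best type ("C15") differs
#' from the true marker by exactly one base — a 340/341 identity for a
#' 341-bp marker — and the remaining entries are clearly worse.
#'
#' @param marker the planted marker sequence.
#' @param n_subs named integer vector: substitutions per panel entry.
#' @return `data.frame(name, seq)`.
#' @export
make_marker_panel <- function(marker,
                              n_subs = c(C15 = 1L, C1 = 15L, C3 = 25L,
                                         D1 = 40L)) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(marker)
  entries <- vapply(n_subs, function(k) {
    pos <- sort(sample.int(L, k))
    s <- strsplit(marker, "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    paste(s, collapse = "")
  }, "")
  data.frame(name = names(n_subs), seq = unname(entries),
             stringsAsFactors = FALSE)
}
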