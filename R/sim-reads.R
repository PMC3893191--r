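# Read-level simulation: diploid alternate haplotypes, paired reads with
# engineered QC defects, and marker tiling reads.

# Evenly-anchored random positions with guaranteed spacing `gap`, so indel
# edits (and their VCF anchor bases) never collide.
sample_spaced_positions <- function(lo, hi, n, gap) {
  if (n == 0) return(integer(0))
  if (hi < lo) stop("empty position window")
  offset <- sample.int(gap, 1L) - 1L
  grid <- seq(lo + offset, hi, by = gap)
  if (length(grid) < n)
    stop("cannot place ", n, " variants with spacing ", gap,
         " in [", lo, ", ", hi, "]")
  sort(grid[sample.int(length(grid), n)])
}

#' Mutate one haplotype into a diploid alternate
#'
#' Creates the second haplotype of a diploid contig by editing the reference
#' at a composite rate: `het_rate` counts SNP sites plus indel base pairs per
#' reference bp, with `snp_frac` of the polymorphic bp coming from SNPs and
#' the rest from 1-`max_indel` bp insertions/deletions (uniform sizes,
#' 50/50 orientation). Variants are returned in VCF-style representation
#' (indels left-anchored on the preceding reference base).
#'
#' @param seq reference contig sequence.
#' @param config a [sim_config()].
#' @return list with `alt` (the alternate haplotype) and `variants`
#'   (`data.frame(pos, kind, ref, alt, affected_bp)` on reference
#'   coordinates).
#' @export
mutate_haplotype <- function(seq, config) {
  len <- nchar(seq)
  target_bp <- round(len * config$het_rate)
  if (target_bp == 0)
    return(list(alt = seq,
                variants = data.frame(pos = integer(0), kind = character(0),
                                      ref = character(0), alt = character(0),
                                      affected_bp = integer(0))))
  indel_target <- round(target_bp * (1 - config$snp_frac))
  sizes <- integer(0)
  while (sum(sizes) < indel_target)
    sizes <- c(sizes, sample.int(config$max_indel, 1L))
  n_snp <- max(0L, target_bp - sum(sizes))
  n_ev <- n_snp + length(sizes)
  gap <- config$max_indel + 2L
  pos <- sample_spaced_positions(2L, len - config$max_indel - 1L, n_ev, gap)
  kind <- sample(c(rep("SNP", n_snp), rep("INDEL", length(sizes))))
  sizes_at <- integer(n_ev)
  sizes_at[kind == "INDEL"] <- sizes[sample.int(length(sizes))]

  bases <- c("A", "C", "G", "T")
  ref_a <- alt_a <- character(n_ev)
  vpos <- integer(n_ev)
  aff <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    p <- pos[i]
    if (kind[i] == "SNP") {
      b <- substr(seq, p, p)
      ref_a[i] <- b
      alt_a[i] <- sample(setdiff(bases, b), 1L)
      vpos[i] <- p
      aff[i] <- 1L
    } else {
      s <- sizes_at[i]
      anchor <- substr(seq, p - 1L, p - 1L)
      if (runif(1) < 0.5) {            # deletion of seq[p .. p+s-1]
        ref_a[i] <- substr(seq, p - 1L, p + s - 1L)
        alt_a[i] <- anchor
      } else {                          # insertion after p-1
        ref_a[i] <- anchor
        alt_a[i] <- paste0(anchor, paste(sample(bases, s, replace = TRUE),
                                         collapse = ""))
      }
      vpos[i] <- p - 1L
      aff[i] <- s
    }
  }
  # assemble the alternate haplotype in one pass over inter-edit segments
  parts <- character(2L * n_ev + 1L)
  prev <- 1L
  for (i in seq_len(n_ev)) {
    parts[2L * i - 1L] <- substr(seq, prev, vpos[i] - 1L)
    parts[2L * i] <- alt_a[i]
    prev <- vpos[i] + nchar(ref_a[i])
  }
  parts[2L * n_ev + 1L] <- substr(seq, prev, len)
  alt_seq <- paste(parts, collapse = "")
  list(alt = alt_seq,
       variants = data.frame(pos = vpos, kind = kind, ref = ref_a,
                             alt = alt_a, affected_bp = aff,
                             stringsAsFactors = FALSE))
}

#' Simulate paired reads with engineered QC defects
#'
#' Each contig becomes a diploid pair of haplotypes (see
#' [mutate_haplotype()]); read pairs are drawn from both haplotypes with
#' fragment length `insert_len`. Deterministic fractions of pairs receive
#' engineered defects that exercise the read-QC rules: exact PCR-duplicate
#' copies, adapter read-through on mate 1, a 10-bp Q10 tail (trimmed,
#' survives the 80-bp pair filter), and a 25-bp Q10 tail (trimmed below
#' 80 bp, dropped). Base quality is Q37 everywhere else, so the Q20 trim
#' rule acts deterministically.
#'
#' @param contigs contig data frame (`id`, `seq`; see [contig_records()]).
#' @param config a [sim_config()]; `read_len` must not exceed the shortest
#'   contig, `het_rate` above 0.2 is rejected.
#' @return list with `pairs` (id, contig_id, haplotype, seq/qual per mate,
#'   defect label), `variants` (truth variants per contig, reference
#'   coordinates), `alt_haplotypes`, and `expected_qc_survivors` — the
#'   number of distinct pairs a Q20 trim / adapter strip / duplicate
#'   removal / 80-bp pair filter chain must retain.
#' @export
make_read_pairs <- function(contigs, config) {
  if (config$het_rate > 0.2)
    stop("het_rate > 0.2 is rejected: unrealistic and breaks mapping assumptions")
  if (any(contigs$length < config$read_len))
    stop("read_len must not exceed any source contig length")
  rl <- config$read_len
  n <- config$n_read_pairs

  muts <- lapply(seq_len(nrow(contigs)), function(i)
    mutate_haplotype(contigs$seq[i], config))
  alt <- vapply(muts, `[[`, "", "alt")
  names(alt) <- contigs$id
  variants <- do.call(rbind, lapply(seq_along(muts), function(i) {
    v <- muts[[i]]$variants
    if (nrow(v)) cbind(contig_id = contigs$id[i], v,
                       stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(variants))
    variants <- data.frame(contig_id = character(0), pos = integer(0),
                           kind = character(0), ref = character(0),
                           alt = character(0), affected_bp = integer(0))

  pick <- sample.int(nrow(contigs), n, replace = TRUE, prob = contigs$length)
  hap <- sample(c("ref", "alt"), n, replace = TRUE)
  seq1 <- seq2 <- character(n)
  for (i in seq_len(n)) {
    h <- if (hap[i] == "ref") contigs$seq[pick[i]] else alt[[pick[i]]]
    hl <- nchar(h)
    ins <- min(config$insert_len, hl)
    fs <- sample.int(hl - ins + 1L, 1L)
    seq1[i] <- substr(h, fs, fs + rl - 1L)
    seq2[i] <- revcomp(substr(h, fs + ins - rl, fs + ins - 1L))
  }
  q37 <- strrep(rawToChar(as.raw(33 + 37)), rl)
  qual1 <- qual2 <- rep(q37, n)

  n_short <- round(config$shortfail_frac * n)
  n_lowq <- round(config$lowq_frac * n)
  n_adapt <- round(config$adapter_frac * n)
  idx <- sample.int(n)
  i_short <- idx[seq_len(n_short)]
  i_lowq <- idx[n_short + seq_len(n_lowq)]
  i_adapt <- idx[n_short + n_lowq + seq_len(n_adapt)]
  defect <- rep("clean", n)
  defect[i_short] <- "short_tail"
  defect[i_lowq] <- "lowq_tail"
  defect[i_adapt] <- "adapter"

  q10 <- rawToChar(as.raw(33 + 10))
  set_tail <- function(q, k) paste0(substr(q, 1L, rl - k), strrep(q10, k))
  qual1[i_short] <- set_tail(q37, 25L)
  qual1[i_lowq] <- set_tail(q37, 10L)
  alen <- nchar(config$adapter_seq)
  seq1[i_adapt] <- paste0(substr(seq1[i_adapt], 1L, rl - alen),
                          config$adapter_seq)

  n_dup <- round(config$duplicate_frac * n)
  dup_src <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)

  pairs <- data.frame(
    id = sprintf("read_%06d", seq_len(n + n_dup)),
    contig_id = contigs$id[c(pick, pick[dup_src])],
    haplotype = c(hap, hap[dup_src]),
    seq1 = c(seq1, seq1[dup_src]), qual1 = c(qual1, qual1[dup_src]),
    seq2 = c(seq2, seq2[dup_src]), qual2 = c(qual2, qual2[dup_src]),
    defect = c(defect, rep("duplicate", n_dup)),
    stringsAsFactors = FALSE)

  # truth bookkeeping for the QC chain: final mate-1 sequence after the
  # engineered defect is processed by trim (Q10 tails) and adapter stripping
  final1 <- c(seq1, seq1[dup_src])
  cut <- integer(n)
  cut[i_short] <- 25L
  cut[i_lowq] <- 10L
  cut[i_adapt] <- alen
  cutall <- c(cut, cut[dup_src])
  final1 <- substr(final1, 1L, rl - cutall)
  survives <- (rl - cutall) >= 80L & rl >= 80L
  key <- paste(final1, pairs$seq2, sep = "|")
  expected <- sum(survives & !duplicated(key))

  list(pairs = pairs, variants = variants, alt_haplotypes = alt,
       expected_qc_survivors = expected)
}

#' Plant marker tiling reads into a read set
#'
#' Appends error-free reads tiling the primer-flanked marker at half-read
#' steps (first and last tiles contain the primers, adjacent tiles overlap
#' by at least half a read); alternate tiles are emitted reverse
#' complemented so assembly must handle both orientations.
#'
#' @param reads single-end read data frame (`id`, `seq`, `qual`) — typically
#'   the symbiont-origin read pool.
#' @param config a [sim_config()]; the marker must be at least one read long.
#' @return list with `reads` (input plus marker tiles), `marker` (the planted
#'   sequence) and `tile_starts`.
#' @export
plant_marker <- function(reads, config) {
  marker <- make_marker(config)
  L <- nchar(marker)
  rl <- config$read_len
  if (L < rl) stop("marker shorter than read_len")
  step <- max(1L, rl %/% 2L)
  starts <- unique(c(seq(1L, L - rl + 1L, by = step), L - rl + 1L))
  tiles <- substring(marker, starts, starts + rl - 1L)
  flip <- seq_along(tiles) %% 2L == 0L
  tiles[flip] <- revcomp(tiles[flip])
  q37 <- strrep(rawToChar(as.raw(33 + 37)), rl)
  marker_reads <- data.frame(id = sprintf("marker_%03d", seq_along(tiles)),
                             seq = tiles, qual = rep(q37, length(tiles)),
                             stringsAsFactors = FALSE)
  list(reads = rbind(reads, marker_reads), marker = marker,
       tile_starts = starts)
}
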