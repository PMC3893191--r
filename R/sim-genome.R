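#' Simulate a source genome with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc_target`/2 and
#' P(A) = P(T) = (1 - `gc_target`)/2, so the realised GC fraction
#' concentrates around the target at rate sqrt(gc(1-gc)/length). Randomness
#' comes from R's global RNG; seed with `set.seed()` (or use
#' [simulate_holobiont()], which seeds once from its config).
#'
#' @param length genome length in bp (> 0).
#' @param gc_target GC fraction strictly inside \[0, 1\] (the degenerate
#'   endpoints 0 and 1 are allowed and produce AT-only / GC-only sequence).
#' @return a single DNA string.
#' @export
make_genome <- function(length, gc_target) {
  if (length(length) != 1 || is.na(length) || length <= 0)
    stop("genome length must be a single positive number")
  if (gc_target < 0 || gc_target > 1)
    stop("gc_target must lie in [0, 1]")
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Draw contigs as uniformly placed substrings of a genome
#'
#' Contig identifiers carry no information about the source genome; origin
#' bookkeeping belongs to the caller's truth table.
#'
#' @param genome DNA string.
#' @param n number of contigs (0 gives an empty record set).
#' @param len_range integer pair (min, max) contig length in bp; max must
#'   not exceed the genome length.
#' @param prefix identifier prefix.
#' @return `data.frame(id, seq, length, gc, start)` where `start` is the
#'   1-based placement on the genome (truth-table material).
#' @export
make_contigs <- function(genome, n, len_range, prefix = "ctg") {
  L <- nchar(genome)
  stopifnot(length(len_range) == 2, len_range[1] >= 1)
  if (len_range[2] > L) stop("max contig length exceeds genome length")
  if (n == 0) {
    out <- contig_records(character(0), character(0))
    out$start <- integer(0)
    return(out)
  }
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
  seqs <- substring(genome, starts, starts + lens - 1L)
  out <- contig_records(seqs, sprintf("%s_%05d", prefix, seq_len(n)))
  out$start <- starts
  out
}

#' Construct a primer-flanked marker sequence
#'
#' The marker starts with the forward primer and ends with the reverse
#' complement of the reverse primer, with a random core at the configured GC
#' in between — the layout of a PCR amplicon such as the ITS-2 region used
#' for symbiont typing.
#'
#' @param config a [sim_config()].
#' @return a DNA string of `config$marker_len` bp.
#' @export
make_marker <- function(config) {
  if (!is.null(config$marker_seq)) {
    m <- config$marker_seq
    if (!grepl(config$primer_fwd, m, fixed = TRUE) ||
        !grepl(revcomp(config$primer_rev), m, fixed = TRUE))
      stop("supplied marker_seq must contain primer_fwd and revcomp(primer_rev)")
    return(m)
  }
  core_len <- config$marker_len - nchar(config$primer_fwd) -
    nchar(config$primer_rev)
  if (core_len < 0) stop("marker_len shorter than the two primers")
  core <- make_genome(core_len, config$symbiont_gc)
  paste0(config$primer_fwd, core, revcomp(config$primer_rev))
}
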