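#' Configuration for the synthetic holobiont generator
#'
#' Bundles every tunable of the truth-labelled synthetic dataset. The
#' defaults are the study conditions the package is validated under: a host
#' genome with mean exonic GC near 40% and a symbiont genome near 53%, a
#' within-colony heterozygosity of 1.0% (composite SNP-site plus indel-bp
#' rate), 100-bp paired reads, and a 341-bp primer-flanked ITS-2-like marker
#' planted in symbiont read space.
#'
#' @param seed integer seed; the same seed yields byte-identical outputs.
#' @param host_gc,symbiont_gc target GC fractions of the two source genomes.
#' @param genome_len length (bp) of each simulated source genome.
#' @param n_host_contigs,n_symbiont_contigs contigs drawn from each genome.
#' @param contig_len_range contig length range (bp); the minimum is
#'   deliberately below 200 bp so the contig length filter has work to do.
#' @param het_rate composite polymorphism rate between the two haplotypes:
#'   (SNP sites + indel bp) per bp. Rejected above 0.2.
#' @param snp_frac fraction of polymorphic bp contributed by SNPs (the
#'   remainder comes from 1-5 bp indels).
#' @param max_indel maximum indel size (bp).
#' @param read_len read length (bp).
#' @param n_read_pairs total read pairs drawn across contigs.
#' @param insert_len fragment length (bp) for paired reads.
#' @param duplicate_frac fraction of pairs emitted a second time as exact
#'   PCR-duplicate copies.
#' @param adapter_frac fraction of pairs whose first mate reads through into
#'   the adapter (3' end replaced by `adapter_seq`).
#' @param lowq_frac fraction of pairs given a 10-bp Q10 tail on mate 1
#'   (trimmed but still long enough to survive the pair-length filter).
#' @param shortfail_frac fraction of pairs given a 25-bp Q10 tail on mate 1
#'   (trimmed below the 80-bp pair filter, hence dropped).
#' @param adapter_seq adapter contaminant sequence.
#' @param primer_fwd,primer_rev marker primer sequences (the published
#'   ITS-2 genotyping primers are cited, not printed, in the source study;
#'   these are configurable stand-ins).
#' @param marker_len length of the planted marker (bp).
#' @param marker_seq optional explicit marker sequence; when `NULL` a marker
#'   of `marker_len` bp with `primer_fwd` at the 5' end and the reverse
#'   complement of `primer_rev` at the 3' end is generated from the seed.
#' @param low_mq_frac,bad_depth_frac fractions of simulated variant records
#'   engineered to fail the mapping-quality and depth filters.
#' @param pathway_gap_plan nested list `amino_acid -> organism -> KO ids`
#'   to delete when building the per-organism KO tables; defaults to
#'   [default_gap_plan()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_gc = 0.40, symbiont_gc = 0.53,
                       genome_len = 500000L,
                       n_host_contigs = 1000L, n_symbiont_contigs = 1000L,
                       contig_len_range = c(150L, 2500L),
                       het_rate = 0.010, snp_frac = 0.955, max_indel = 5L,
                       read_len = 100L, n_read_pairs = 4000L, insert_len = 250L,
                       duplicate_frac = 0.05, adapter_frac = 0.03,
                       lowq_frac = 0.05, shortfail_frac = 0.04,
                       adapter_seq = "AGATCGGAAGAGC",
                       primer_fwd = "GTGAATTGCAGAACTCCGTG",
                       primer_rev = "CCTCCGCTTACTTATATGCTT",
                       marker_len = 341L, marker_seq = NULL,
                       low_mq_frac = 0.02, bad_depth_frac = 0.02,
                       pathway_gap_plan = default_gap_plan()) {
  fr <- c(host_gc = host_gc, symbiont_gc = symbiont_gc, het_rate = het_rate,
          snp_frac = snp_frac, duplicate_frac = duplicate_frac,
          adapter_frac = adapter_frac, lowq_frac = lowq_frac,
          shortfail_frac = shortfail_frac, low_mq_frac = low_mq_frac,
          bad_depth_frac = bad_depth_frac)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (host_gc <= 0 || host_gc >= 1 || symbiont_gc <= 0 || symbiont_gc >= 1)
    stop("GC targets must lie strictly inside (0, 1)")
  if (het_rate > 0.2)
    stop("het_rate > 0.2 is rejected: unrealistic and breaks mapping assumptions")
  stopifnot(length(contig_len_range) == 2, contig_len_range[1] > 0,
            contig_len_range[1] <= contig_len_range[2],
            contig_len_range[2] <= genome_len,
            read_len <= contig_len_range[1],
            max_indel >= 1, nchar(adapter_seq) > 0,
            nchar(primer_fwd) > 0, nchar(primer_rev) > 0)
  cfg <- list(seed = as.integer(seed), host_gc = host_gc,
              symbiont_gc = symbiont_gc, genome_len = as.integer(genome_len),
              n_host_contigs = as.integer(n_host_contigs),
              n_symbiont_contigs = as.integer(n_symbiont_contigs),
              contig_len_range = as.integer(contig_len_range),
              het_rate = het_rate, snp_frac = snp_frac,
              max_indel = as.integer(max_indel),
              read_len = as.integer(read_len),
              n_read_pairs = as.integer(n_read_pairs),
              insert_len = as.integer(insert_len),
              duplicate_frac = duplicate_frac, adapter_frac = adapter_frac,
              lowq_frac = lowq_frac, shortfail_frac = shortfail_frac,
              adapter_seq = adapter_seq, primer_fwd = primer_fwd,
              primer_rev = primer_rev, marker_len = as.integer(marker_len),
              marker_seq = marker_seq, low_mq_frac = low_mq_frac,
              bad_depth_frac = bad_depth_frac,
              pathway_gap_plan = pathway_gap_plan)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed,
      sprintf("| GC %.2f/%.2f | %d+%d contigs | het %.3f | %d read pairs\n",
              x$host_gc, x$symbiont_gc, x$n_host_contigs, x$n_symbiont_contigs,
              x$het_rate, x$n_read_pairs))
  invisible(x)
}
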