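#' Simulate a complete truth-labelled holobiont dataset
#'
#' Generates the full synthetic study: two source genomes (host GC ~ 0.40,
#' symbiont GC ~ 0.53), contigs of known origin pooled under
#' origin-agnostic identifiers, diploid paired reads with engineered QC
#' defects, a primer-flanked marker planted in symbiont read space with a
#' matching reference panel, per-organism KO tables with designed pathway
#' gaps, and a truth table tying everything together. Fully deterministic:
#' the same `config$seed` reproduces every output byte for byte.
#'
#' @param config a [sim_config()].
#' @return list with `genomes`, `contigs` (pooled, with truth columns
#'   removed into `truth`), `pairs`, `marker_pool` (symbiont-origin
#'   single-end reads plus marker tiles), `marker`, `panel`, `ko`,
#'   `variants` (truth variants on contig coordinates), `truth`
#'   (`origin` per contig id, `expected_qc_survivors`, `marker_tile_starts`,
#'   deleted KO sets), and the `config`.
#' @export
simulate_holobiont <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  host_genome <- make_genome(config$genome_len, config$host_gc)
  sym_genome <- make_genome(config$genome_len, config$symbiont_gc)

  hc <- make_contigs(host_genome, config$n_host_contigs,
                     config$contig_len_range, prefix = "h")
  sc <- make_contigs(sym_genome, config$n_symbiont_contigs,
                     config$contig_len_range, prefix = "s")
  pooled <- rbind(hc, sc)
  origin <- c(rep("HOST", nrow(hc)), rep("SYMBIONT", nrow(sc)))
  shuffle <- sample.int(nrow(pooled))
  pooled <- pooled[shuffle, , drop = FALSE]
  origin <- origin[shuffle]
  pooled$id <- sprintf("ctg_%05d", seq_len(nrow(pooled)))
  rownames(pooled) <- NULL
  contigs <- pooled[, c("id", "seq", "length", "gc")]
  truth_origin <- setNames(origin, contigs$id)

  rp <- make_read_pairs(contigs, config)

  sym_pairs <- rp$pairs[truth_origin[rp$pairs$contig_id] == "SYMBIONT", ,
                        drop = FALSE]
  sym_single <- data.frame(
    id = c(paste0(sym_pairs$id, "/1"), paste0(sym_pairs$id, "/2")),
    seq = c(sym_pairs$seq1, sym_pairs$seq2),
    qual = c(sym_pairs$qual1, sym_pairs$qual2),
    stringsAsFactors = FALSE)
  pm <- plant_marker(sym_single, config)
  panel <- make_marker_panel(pm$marker)

  models <- load_pathway_models()
  ko <- make_ko_tables(models, config$pathway_gap_plan,
                       host_contig_ids = contigs$id[truth_origin == "HOST"],
                       symbiont_contig_ids =
                         contigs$id[truth_origin == "SYMBIONT"])

  list(genomes = list(host = host_genome, symbiont = sym_genome),
       contigs = contigs, pairs = rp$pairs,
       marker_pool = pm$reads, marker = pm$marker, panel = panel,
       ko = ko, variants = rp$variants,
       truth = list(origin = truth_origin,
                    expected_qc_survivors = rp$expected_qc_survivors,
                    marker_tile_starts = pm$tile_starts,
                    deleted_kos = ko$deleted,
                    alt_haplotypes = rp$alt_haplotypes),
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Serialises the synthetic dataset in standard formats: genomes and
#' contigs as FASTA, reads as paired FASTQ (Phred+33), the marker pool as
#' FASTQ, the marker panel as FASTA, truth tables and KO tables as TSV, the
#' configuration as YAML, and a JSON run manifest recording the seed and
#' all parameters.
#'
#' @param sim output of [simulate_holobiont()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta_contigs(data.frame(id = c("host_genome", "symbiont_genome"),
                                 seq = unlist(sim$genomes)), p("genomes.fasta"))
  write_fasta_contigs(sim$contigs, p("contigs.fasta"))
  r1 <- data.frame(id = paste0(sim$pairs$id, "/1"), seq = sim$pairs$seq1,
                   qual = sim$pairs$qual1)
  r2 <- data.frame(id = paste0(sim$pairs$id, "/2"), seq = sim$pairs$seq2,
                   qual = sim$pairs$qual2)
  write_fastq_reads(r1, p("reads_1.fastq"))
  write_fastq_reads(r2, p("reads_2.fastq"))
  write_fastq_reads(sim$marker_pool, p("marker_pool.fastq"))
  write_fasta_contigs(data.frame(id = sim$panel$name, seq = sim$panel$seq),
                      p("marker_panel.fasta"))
  utils::write.table(
    data.frame(contig_id = names(sim$truth$origin),
               origin = unname(sim$truth$origin)),
    p("truth_origin.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$variants, p("truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ko$host, p("ko_host.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ko$symbiont, p("ko_symbiont.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$pathway_gap_plan <- NULL
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  jsonlite::write_json(
    list(seed = sim$config$seed,
         n_contigs = nrow(sim$contigs),
         n_read_pairs = nrow(sim$pairs),
         marker_len = nchar(sim$marker),
         expected_qc_survivors = sim$truth$expected_qc_survivors),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
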