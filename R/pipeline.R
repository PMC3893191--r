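#' Run the full holobiont analysis end-to-end on a synthetic dataset
#'
#' Executes every stage in study order on a freshly simulated dataset: read
#' QC (Q20 trim, adapter strip, duplicate removal, 80-bp pair filter),
#' contig QC (200-bp length filter, ORF-level redundancy removal), native
#' alignment of contigs against both source genomes, e-value cutoff scan
#' and exclusive-hit binning, GC-mixture validation, annotation-evidence
#' accounting, polymorphism-rate estimation on the host bin, marker
#' recruitment/assembly/typing, and amino-acid complementarity inference.
#' Every number in the manifest is re-derivable from the returned stage
#' outputs.
#'
#' @param config a [sim_config()]; all randomness funnels through its seed.
#' @param out_dir optional directory; when given, stage tables and the JSON
#'   run manifest are written there.
#' @param evalue_cutoffs cutoffs scanned before binning.
#' @return list of stage results (`sim`, `qc`, `contigs`, `scan`, `bins`,
#'   `gc_fit`, `fractions`, `accuracy`, `annotation`, `polymorphism`,
#'   `marker`, `pathways`, `manifest`).
#' @export
run_holobiont <- function(config = sim_config(), out_dir = NULL,
                          evalue_cutoffs = c(1e-1, 1e-2, 1e-3, 1e-4, 1e-5,
                                             1e-10)) {
  sim <- simulate_holobiont(config)

  qc <- qc_reads(sim$pairs, q_threshold = 20, min_len = 80,
                 adapter = config$adapter_seq)

  kept <- length_filter(sim$contigs, 200)
  kept <- dedup_contigs(kept, 0.95)
  universe <- kept$id

  queries <- setNames(kept$seq, kept$id)
  hits_host <- native_search(queries, sim$genomes$host, "host_genome")
  hits_sym <- native_search(queries, sim$genomes$symbiont, "symbiont_genome")

  scan <- scan_cutoffs(hits_host, hits_sym, universe, evalue_cutoffs)
  cutoff <- attr(scan, "selected")
  bins <- assign_bins(hits_host, hits_sym, universe, cutoff)
  fractions <- dataset_symbiont_fraction(bins)
  gc_fit <- gc_mixture(kept$gc, k = 2)

  truth <- sim$truth$origin[bins$contig_id]
  called <- bins$bin %in% c("HOST", "SYMBIONT")
  accuracy <- sum(as.character(bins$bin[called]) == truth[called]) /
    max(1, sum(called))

  ev_tab <- function(h) data.frame(contig_id =
                                     unique(h$query_id[h$evalue <= cutoff]))
  kegg <- rbind(sim$ko$host, sim$ko$symbiont)
  kegg <- kegg[kegg$contig_id %in% universe, , drop = FALSE]
  annotation <- merge_evidence(universe,
                               list(HOST_GENOME = ev_tab(hits_host),
                                    SYMBIONT_GENOME = ev_tab(hits_sym),
                                    KEGG = kegg))

  host_bin <- kept[kept$id %in% bins$contig_id[bins$bin == "HOST"], ,
                   drop = FALSE]
  vtruth <- sim$variants[sim$variants$contig_id %in% host_bin$id, ,
                         drop = FALSE]
  vcf_path <- tempfile(fileext = ".vcf")
  write_variant_vcf(vtruth, config, vcf_path)
  vrec <- read_variants(vcf_path)
  vfilt <- filter_variants(vrec)
  polymorphism <- summarize_variants(vfilt, host_bin)
  unlink(vcf_path)

  recruited <- recruit_reads(sim$marker_pool, config$primer_fwd,
                             config$primer_rev)
  asm <- assemble_marker(recruited, min_overlap = 30,
                         extension_reads = sim$marker_pool)
  consensus <- orient_by_primer(asm$consensus, config$primer_fwd)
  typing <- type_marker(consensus, sim$panel)
  marker_reads <- sim$marker_pool[grepl("^marker_", sim$marker_pool$id), ,
                                  drop = FALSE]
  n_marker_variants <- marker_variant_check(rbind(recruited, marker_reads),
                                            consensus)

  pathways <- complementarity(sim$ko$host$ko, sim$ko$symbiont$ko,
                              load_pathway_models(), tolerance = 2)

  manifest <- list(
    seed = config$seed,
    reads = as.list(qc$log),
    expected_qc_survivors = sim$truth$expected_qc_survivors,
    contigs = list(simulated = nrow(sim$contigs),
                   after_length_filter = sum(sim$contigs$length >= 200),
                   after_dedup = nrow(kept)),
    binning = list(cutoff = cutoff,
                   counts = as.list(table(bins$bin)),
                   fractions = as.list(fractions),
                   accuracy = accuracy),
    gc_means = gc_fit$means,
    annotation = list(n_annotated = annotation$n_annotated,
                      pct_annotated = annotation$pct_annotated),
    polymorphism = polymorphism[c("n_snp_sites", "n_indels",
                                  "indel_bp_total", "denominator_bp",
                                  "rate")],
    marker = list(length = nchar(consensus), best_type = typing$best_type,
                  identical_bp = typing$identical_bp,
                  aligned_bp = typing$aligned_bp,
                  n_variants = n_marker_variants),
    pathway_classes = as.list(pathways$summary$overall),
    pathway_classes_essential = as.list(pathways$summary$essential))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scan, file.path(out_dir, "cutoff_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bins, file.path(out_dir, "bin_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pathways$table,
                       file.path(out_dir, "aa_complementarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(sim = sim, qc = qc, contigs = kept, scan = scan, bins = bins,
       gc_fit = gc_fit, fractions = fractions, accuracy = accuracy,
       annotation = annotation, polymorphism = polymorphism,
       marker = list(recruited = recruited, consensus = consensus,
                     typing = typing, n_variants = n_marker_variants),
       pathways = pathways, manifest = manifest)
}
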