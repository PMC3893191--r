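#' Read variant records from a VCF
#'
#' Parses SNPs and indels with their depth (DP) and mapping quality (MQ),
#' taken from INFO (preferred) or, if absent there, from the first sample's
#' FORMAT fields. Indel affected bp is the length difference between the
#' reference and alternate alleles; SNPs affect one bp. Multi-allelic sites
#' count once (the first alternate allele is used), matching a per-position
#' reading of SNP counts.
#'
#' @param path VCF file (plain or bgzipped).
#' @return `data.frame(contig_id, pos, kind, ref_allele, alt_allele,
#'   affected_bp, depth, map_quality)`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt1 <- vapply(strsplit(fix[, "ALT"], ",", fixed = TRUE), `[`, "", 1)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  has_gt <- !is.null(v@gt) && length(dim(v@gt)) == 2 && ncol(v@gt) > 1
  if (all(is.na(dp)) && has_gt)
    dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "DP")[, 1]))
  if (all(is.na(mq)) && has_gt)
    mq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "MQ")[, 1]))
  ref <- fix[, "REF"]
  kind <- ifelse(nchar(ref) == nchar(alt1) & nchar(ref) == 1, "SNP", "INDEL")
  aff <- ifelse(kind == "SNP", 1L, abs(nchar(ref) - nchar(alt1)))
  bad <- which(aff < 1 | is.na(alt1))
  if (length(bad))
    stop("malformed variant record at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  data.frame(contig_id = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             kind = kind, ref_allele = ref, alt_allele = alt1,
             affected_bp = as.integer(aff), depth = dp, map_quality = mq,
             stringsAsFactors = FALSE)
}

#' Filter variants by the study's quality rules
#'
#' A record is kept when mapping quality is at least `min_mq`, depth lies in
#' \[`min_depth`, `max_depth`\] and, for indels, the affected size does not
#' exceed `max_indel_bp`. All boundaries are inclusive. Idempotent and
#' order-preserving.
#'
#' @param records variant data frame from [read_variants()].
#' @param min_mq minimum mapping quality (Phred-scaled).
#' @param min_depth,max_depth depth bounds (reads).
#' @param max_indel_bp maximum indel size retained (bp).
#' @return filtered records.
#' @export
filter_variants <- function(records, min_mq = 25, min_depth = 10,
                            max_depth = 200, max_indel_bp = 5) {
  keep <- records$map_quality >= min_mq &
    records$depth >= min_depth & records$depth <= max_depth &
    (records$kind == "SNP" | records$affected_bp <= max_indel_bp)
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Within-colony polymorphism rate
#'
#' The composite rate combining SNP site counts with indel base pairs:
#' 100 * (SNP sites + indel bp) / denominator bp, rounded half-up to one
#' decimal. Using indel bp (not indel event counts) in the numerator is the
#' formula that reproduces the study's printed 1.0% exactly.
#'
#' @param n_snp_sites number of SNP positions.
#' @param indel_bp_total total affected indel base pairs.
#' @param denominator_bp assessed base pairs (> 0); the full length of the
#'   host contig set.
#' @return percentage, one decimal.
#' @export
polymorphism_rate <- function(n_snp_sites, indel_bp_total, denominator_bp) {
  if (denominator_bp <= 0) stop("denominator_bp must be positive")
  round_half_up(100 * (n_snp_sites + indel_bp_total) / denominator_bp, 1)
}

#' Summarise filtered variants over a contig set
#'
#' @param records filtered variant records.
#' @param contigs contig data frame defining the denominator (total bp of
#'   the set); every record's contig must belong to it.
#' @return list with `n_snp_sites`, `n_indels`, `indel_bp_total`,
#'   `denominator_bp`, `rate` (percent, one decimal).
#' @export
summarize_variants <- function(records, contigs) {
  foreign <- setdiff(unique(records$contig_id), contigs$id)
  if (length(foreign))
    stop("variant records reference unknown contigs: ",
         paste(head(foreign, 5), collapse = ", "))
  snp <- records[records$kind == "SNP", , drop = FALSE]
  ind <- records[records$kind == "INDEL", , drop = FALSE]
  n_snp <- length(unique(paste(snp$contig_id, snp$pos)))
  indel_bp <- sum(ind$affected_bp)
  denom <- sum(as.numeric(contigs$length))
  list(n_snp_sites = n_snp, n_indels = nrow(ind),
       indel_bp_total = indel_bp, denominator_bp = denom,
       rate = polymorphism_rate(n_snp, indel_bp, denom))
}

#' Write simulated variant records as a VCF
#'
#' Generator-side companion to [read_variants()]: serialises truth variants
#' with simulated DP and MQ INFO fields. Deterministic fractions of records
#' are engineered to fail the mapping-quality or depth filters so the
#' filtering rules have work to do.
#'
#' @param variants truth variant table (`contig_id`, `pos`, `ref`, `alt`).
#' @param config a [sim_config()] (supplies the engineered failure
#'   fractions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, config, path) {
  n <- nrow(variants)
  mq <- rep(60, n)
  dp <- 10L + rpois(n, 30)
  dp <- pmin(dp, 200L)
  n_mq <- round(config$low_mq_frac * n)
  n_dp <- round(config$bad_depth_frac * n)
  idx <- sample.int(n)
  i_mq <- idx[seq_len(n_mq)]
  i_dp <- idx[n_mq + seq_len(n_dp)]
  if (n_mq) mq[i_mq] <- sample(5:24, n_mq, replace = TRUE)
  if (n_dp) dp[i_dp] <- sample(c(3:9, 201:260), n_dp, replace = TRUE)
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\tDP=%d;MQ=%d",
                     variants$contig_id, variants$pos, variants$ref,
                     variants$alt, dp, mq))
  writeLines(lines, path)
  invisible(path)
}
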