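marker_fixture <- function(seed = 19) {
  cfg <- sim_config(seed = seed)
  set.seed(seed)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0))
  pm <- plant_marker(empty, cfg)
  list(cfg = cfg, reads = pm$reads, marker = pm$marker)
}

test_that("primer recruitment requires exact matches on either strand", {
  fx <- marker_fixture()
  cfg <- fx$cfg
  tailseq <- strrep("T", 60)
  reads <- data.frame(
    id = c("fwd", "mm", "rc_rev", "plain"),
    seq = c(paste0(cfg$primer_fwd, tailseq),
            paste0(sub("^.", "T", sub("^G", "A", cfg$primer_fwd)), tailseq),
            paste0(tailseq, revcomp(cfg$primer_rev)),
            strrep("ACGT", 20)),
    qual = strrep("I", c(80, 80, 81, 80)),
    stringsAsFactors = FALSE)
  got <- recruit_reads(reads, cfg$primer_fwd, cfg$primer_rev)
  expect_setequal(got$id, c("fwd", "rc_rev"))
  # idempotent
  expect_identical(recruit_reads(got, cfg$primer_fwd, cfg$primer_rev), got)
})

test_that("one-mismatch primer copies are not recruited", {
  fx <- marker_fixture()
  p <- fx$cfg$primer_fwd
  mut <- paste0(substr(p, 1, 10),
                chartr("ACGT", "GTAC", substr(p, 11, 11)),
                substr(p, 12, nchar(p)))
  reads <- data.frame(id = "x", seq = paste0(mut, strrep("A", 50)),
                      qual = strrep("I", nchar(mut) + 50))
  expect_equal(nrow(recruit_reads(reads, p, fx$cfg$primer_rev)), 0)
})

test_that("greedy overlap assembly reconstructs the planted marker exactly", {
  fx <- marker_fixture()
  asm <- assemble_marker(fx$reads, min_overlap = 30)
  consensus <- orient_by_primer(asm$consensus, fx$cfg$primer_fwd)
  expect_identical(consensus, fx$marker)
  expect_equal(asm$length, 341)
  expect_false(asm$no_overlap_warning)
})

test_that("assembly is invariant to read input order on clean tilings", {
  fx <- marker_fixture()
  set.seed(1)
  for (rep in 1:3) {
    shuffled <- fx$reads[sample.int(nrow(fx$reads)), , drop = FALSE]
    asm <- assemble_marker(shuffled, min_overlap = 30)
    expect_identical(orient_by_primer(asm$consensus, fx$cfg$primer_fwd),
                     fx$marker)
  }
})

test_that("assembly degenerate cases behave as documented", {
  one <- assemble_marker(data.frame(seq = "ACGTACGTACGT"))
  expect_identical(one$consensus, "ACGTACGTACGT")

  set.seed(2)
  a <- rand_dna(60); b <- rand_dna(60)
  ov <- 30
  b <- paste0(substr(a, 60 - ov + 1, 60), rand_dna(40))
  two <- assemble_marker(data.frame(seq = c(a, b)), min_overlap = 30)
  expect_equal(two$length, 60 + 70 - ov)

  disjoint <- assemble_marker(data.frame(seq = c(strrep("A", 50),
                                                 strrep("C", 50))),
                              min_overlap = 30)
  expect_true(disjoint$no_overlap_warning)
  expect_equal(disjoint$length, 50)

  expect_error(assemble_marker(data.frame(seq = character(0))), "at least")
})

test_that("typing reports identity against the best panel entry", {
  set.seed(26)
  marker <- rand_dna(341, 0.53)
  panel <- make_marker_panel(marker)
  res <- type_marker(marker, panel)
  expect_identical(res$best_type, "C15")
  expect_equal(res$identical_bp, 340)
  expect_equal(res$aligned_bp, 341)
  expect_false(res$tie)

  exact <- type_marker(panel$seq[1], panel)
  expect_equal(exact$identical_bp, 341)
  expect_equal(exact$aligned_bp, 341)

  # equidistant entries tie, broken by panel order and flagged
  tie_panel <- data.frame(name = c("X", "Y"),
                          seq = c(panel$seq[2], panel$seq[2]))
  tie <- type_marker(marker, tie_panel)
  expect_true(tie$tie)
  expect_identical(tie$best_type, "X")
})

test_that("typing identity matches the dynamic-programming oracle", {
  set.seed(29)
  marker <- rand_dna(200, 0.5)
  panel <- make_marker_panel(marker, n_subs = c(A = 1L, B = 8L, C = 20L))
  res <- type_marker(marker, panel)
  for (i in seq_len(nrow(panel))) {
    want <- oracle_nw(marker, panel$seq[i])
    expect_equal(res$scores$identical_bp[i], want$matches)
  }
  # and under a deletion, where gaps enter the alignment
  del <- paste0(substr(marker, 1, 90), substr(marker, 101, 200))
  got <- type_marker(del, data.frame(name = "ref", seq = marker))
  want <- oracle_nw(del, marker)
  expect_equal(got$identical_bp, want$matches)
  expect_equal(got$aligned_bp, 200)
})

test_that("within-marker variation is zero on clean data, found when mixed", {
  fx <- marker_fixture()
  expect_equal(marker_variant_check(fx$reads, fx$marker), 0)

  # a second allele supported by two reads creates a variant column
  allele2 <- fx$marker
  substr(allele2, 150, 150) <- if (substr(allele2, 150, 150) == "A") "C" else "A"
  extra <- data.frame(id = c("v1", "v2"),
                      seq = rep(substr(allele2, 101, 200), 2),
                      qual = strrep("I", 100))
  mixed <- rbind(fx$reads, extra)
  expect_gte(marker_variant_check(mixed, fx$marker), 1)

  single <- data.frame(id = "s", seq = substr(fx$marker, 1, 100),
                       qual = strrep("I", 100))
  expect_equal(marker_variant_check(single, fx$marker), 0)
})
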