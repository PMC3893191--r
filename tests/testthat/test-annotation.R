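test_that("evidence accounting reproduces union and per-source percentages", {
  universe <- sprintf("c%05d", 1:74997)
  union_n <- 60516
  tabs <- list(
    NR = data.frame(contig_id = universe[1:33935]),
    SWISSPROT = data.frame(contig_id = universe[1:25893]),
    HOST_GENOME = data.frame(contig_id = universe[1:30446]),
    SYMBIONT_GENOME = data.frame(contig_id =
                                   universe[(union_n - 30415 + 1):union_n]))
  ev <- merge_evidence(universe, tabs)
  expect_equal(ev$n_annotated, 60516)
  expect_equal(ev$n_unannotated, 14481)
  expect_equal(ev$pct_annotated, 80.7)
  expect_equal(ev$per_source$pct[ev$per_source$source == "NR"], 45.2)
  expect_equal(ev$per_source$pct[ev$per_source$source == "SWISSPROT"], 34.5)

  # order independence
  ev2 <- merge_evidence(universe, rev(tabs))
  expect_equal(ev2$n_annotated, ev$n_annotated)
  expect_equal(sort(ev2$per_source$n), sort(ev$per_source$n))
})

test_that("term-only sources count per source but not in the union", {
  universe <- c("a", "b", "c", "d")
  ev <- merge_evidence(universe,
                       list(NR = data.frame(contig_id = "a"),
                            KEGG = data.frame(contig_id = c("a", "b"))))
  expect_equal(ev$n_annotated, 1)
  expect_equal(ev$per_source$n[ev$per_source$source == "KEGG"], 2)

  none <- merge_evidence(universe, list(NR = data.frame(contig_id =
                                                          character(0))))
  expect_equal(none$n_annotated, 0)
  expect_equal(none$n_unannotated, 4)

  expect_error(merge_evidence(universe,
                              list(NR = data.frame(contig_id = "zz"))), "zz")
})

test_that("reciprocal best hits follow the best-hit rule in both directions", {
  ab <- rbind(hit_row("a1", "b1", 1e-20, 200), hit_row("a1", "b2", 1e-10, 90),
              hit_row("a2", "b2", 1e-8, 80))
  ba <- rbind(hit_row("b1", "a1", 1e-18, 190), hit_row("b2", "a9", 1e-12, 95),
              hit_row("b2", "a2", 1e-6, 60))
  pairs <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(pairs), 1)              # a2's best b2 prefers a9
  expect_identical(pairs$id_a, "a1")
  expect_identical(pairs$id_b, "b1")

  # significance cutoff applies to both directions
  weak <- reciprocal_best_hits(ab, ba, evalue_cutoff = 1e-30)
  expect_equal(nrow(weak), 0)
})

test_that("RBH matches exhaustive enumeration on random tables", {
  set.seed(64)
  for (rep in 1:5) {
    qa <- sprintf("a%02d", 1:20)
    qb <- sprintf("b%02d", 1:20)
    mk <- function(qs, ss) {
      n <- 60
      data.frame(query_id = sample(qs, n, TRUE),
                 subject_id = sample(ss, n, TRUE),
                 pct_identity = 90, aln_len = 100, mismatches = 0,
                 gap_opens = 0, qstart = 1, qend = 100, sstart = 1,
                 send = 100, evalue = 10^-sample(2:30, n, TRUE),
                 bitscore = sample(50:500, n, TRUE),
                 stringsAsFactors = FALSE)
    }
    ab <- mk(qa, qb); ba <- mk(qb, qa)
    got <- reciprocal_best_hits(ab, ba)
    want <- oracle_rbh(ab, ba)
    expect_equal(got$id_a, want$id_a)
    expect_equal(got$id_b, want$id_b)
    # symmetry: swapping the tables swaps the roles, same pair set
    swapped <- reciprocal_best_hits(ba, ab)
    expect_setequal(paste(swapped$id_b, swapped$id_a),
                    paste(got$id_a, got$id_b))
  }
})

test_that("coverage uses interval union and a strict threshold", {
  pairs <- data.frame(id_a = c("a1", "a2", "a3"),
                      id_b = c("b1", "b2", "b3"),
                      stringsAsFactors = FALSE)
  aln <- rbind(hit_row("a1", "b1", 1e-10, sstart = 1, send = 100),
               hit_row("a2", "b2", 1e-10, sstart = 1, send = 60),
               hit_row("a2", "b2", 1e-10, sstart = 41, send = 100),
               hit_row("a3", "b3", 1e-10, sstart = 1, send = 80))
  lens <- c(b1 = 100, b2 = 100, b3 = 100)
  res <- coverage_filter(pairs, aln, lens, min_cov = 0.80)
  # full span and overlapping-union both give 1.0; exactly 0.80 is dropped
  expect_setequal(res$pairs$id_a, c("a1", "a2"))
  expect_equal(res$pairs$coverage_b, c(1, 1))
  expect_equal(res$n_kept, 2)

  expect_error(coverage_filter(pairs, aln, lens[1:2]), "b3")

  # coverage never exceeds 1 and is monotone under added segments
  more <- rbind(aln, hit_row("a1", "b1", 1e-10, sstart = 20, send = 90))
  res2 <- coverage_filter(pairs[1, ], more, lens)
  expect_lte(res2$pairs$coverage_b, 1)
})
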