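make_universe_hits <- function(n_universe, n_host, n_symbiont, n_overlap,
                               evalue = 1e-6) {
  ids <- sprintf("c%05d", seq_len(n_universe))
  host_ids <- ids[seq_len(n_host)]
  sym_ids <- ids[seq(n_host - n_overlap + 1, n_host - n_overlap + n_symbiont)]
  list(ids = ids,
       host = do.call(rbind, lapply(host_ids, hit_row, s = "refA",
                                    evalue = evalue)),
       symbiont = do.call(rbind, lapply(sym_ids, hit_row, s = "refB",
                                        evalue = evalue)))
}

test_that("exclusive-hit binning partitions the universe", {
  u <- make_universe_hits(200, 80, 70, 15)
  bins <- assign_bins(u$host, u$symbiont, u$ids, 1e-4)
  tab <- table(bins$bin)
  expect_equal(unname(tab[["HOST"]]), 80 - 15)
  expect_equal(unname(tab[["SYMBIONT"]]), 70 - 15)
  expect_equal(unname(tab[["AMBIGUOUS"]]), 15)
  expect_equal(sum(tab), 200)
  expect_equal(nrow(bins), length(u$ids))

  empty <- assign_bins(u$host[0, ], u$symbiont[0, ], u$ids, 1e-4)
  expect_true(all(empty$bin == "UNASSIGNED"))

  stray <- hit_row("not_a_contig", "refA", 1e-9)
  expect_error(assign_bins(stray, u$symbiont[0, ], u$ids, 1e-4),
               "not_a_contig")
})

test_that("multiple alignment rows per contig count once, at any cutoff", {
  ids <- c("a", "b", "c")
  hh <- rbind(hit_row("a", "refA", 1e-9), hit_row("a", "refA", 1e-2),
              hit_row("b", "refA", 1e-3))
  hs <- hit_row("b", "refB", 1e-8)
  for (ct in c(1e-1, 1e-4, 1e-8)) {
    bins <- assign_bins(hh, hs, ids, ct)
    expect_equal(nrow(bins), 3)
    expect_equal(sum(table(bins$bin)), 3)
  }
  bins <- assign_bins(hh, hs, ids, 1e-4)
  expect_identical(as.character(bins$bin), c("HOST", "SYMBIONT", "UNASSIGNED"))
})

test_that("cutoff scan rows satisfy their arithmetic and select the peak", {
  # noise: spurious cross-hits at weak e-values create overlap at loose
  # cutoffs; true host hits sit at 1e-5
  hh <- do.call(rbind, lapply(sprintf("h%02d", 1:50), hit_row, s = "refA",
                              evalue = 1e-5))
  noise <- do.call(rbind, lapply(sprintf("h%02d", 1:20), hit_row, s = "refB",
                                 evalue = 1e-3))
  ids <- sprintf("h%02d", 1:50)
  scan <- scan_cutoffs(hh, noise, ids)
  expect_equal(nrow(scan), 6)
  expect_true(all(scan$n_host_only == scan$n_hit_host - scan$n_overlap))
  expect_true(all(scan$n_symbiont_only ==
                    scan$n_hit_symbiont - scan$n_overlap))
  # loose cutoffs admit the noise (host-only 30); 1e-4/1e-5 exclude it
  # (host-only 50); 1e-10 loses the true hits; stricter tie wins
  expect_equal(scan$n_host_only[scan$cutoff == 1e-1], 30)
  expect_equal(scan$n_host_only[scan$cutoff == 1e-4], 50)
  expect_equal(scan$n_host_only[scan$cutoff == 1e-10], 0)
  expect_equal(attr(scan, "selected"), 1e-5)

  one <- scan_cutoffs(hh, noise, ids, cutoffs = 1e-3)
  expect_equal(attr(one, "selected"), 1e-3)

  # identical counts across all cutoffs: the strictest listed cutoff wins
  deep <- do.call(rbind, lapply(ids, hit_row, s = "refA", evalue = 1e-30))
  flat <- scan_cutoffs(deep, noise[0, ], ids)
  expect_equal(length(unique(flat$n_host_only)), 1)
  expect_equal(attr(flat, "selected"), 1e-10)
})

test_that("bin fractions report one-decimal percentages", {
  bins <- data.frame(contig_id = sprintf("c%02d", 1:10),
                     bin = factor(c(rep("HOST", 5), rep("UNASSIGNED", 5)),
                                  levels = c("HOST", "SYMBIONT", "AMBIGUOUS",
                                             "UNASSIGNED")))
  fr <- dataset_symbiont_fraction(bins)
  expect_equal(unname(fr["HOST"]), 50.0)
  expect_equal(unname(fr["SYMBIONT"]), 0.0)
})

test_that("GC mixture recovers a two-component split and degenerates safely", {
  set.seed(77)
  gc <- c(rbinom(1000, 1000, 0.40), rbinom(1000, 1000, 0.53)) / 1000
  fit <- gc_mixture(gc, k = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0.40), 0.01)
  expect_lt(abs(fit$means[2] - 0.53), 0.01)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)

  # k = 1 reduces to the sample mean
  one <- gc_mixture(gc, k = 1)
  expect_equal(one$means, mean(gc), tolerance = 1e-8)

  flat <- gc_mixture(rep(0.45, 50), k = 2)
  expect_true(flat$degenerate)

  expect_error(gc_mixture(gc[1:15], k = 2), "at least")
})

test_that("the EM fit agrees with an independent mixture implementation", {
  set.seed(78)
  gc <- c(rbinom(800, 800, 0.40), rbinom(800, 800, 0.53)) / 800
  fit <- gc_mixture(gc, k = 2)
  library(mclust)    # Mclust resolves helpers in the attached namespace
  mc <- Mclust(gc, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(unname(mc$parameters$mean)),
               tolerance = 0.005)
})

test_that("native search finds exact and strand-flipped alignments", {
  set.seed(55)
  s <- rand_dna(400, 0.5)
  self <- native_search(c(q = s), s, "sub")
  expect_gte(nrow(self), 1)
  top <- self[1, ]
  expect_equal(top$qstart, 1)
  expect_equal(top$qend, 400)
  expect_equal(top$pct_identity, 100)

  # no shared 11-mers on either strand: no hits
  none <- native_search(c(q = strrep("AC", 30)), strrep("AG", 200), "sub")
  expect_equal(nrow(none), 0)

  # reverse-complemented query reported with sstart > send
  q <- revcomp(substr(s, 101, 220))
  minus <- native_search(c(q = q), s, "sub", evalue_max = 1e-3)
  expect_gte(nrow(minus), 1)
  expect_true(minus$sstart[1] > minus$send[1])
  expect_equal(sort(c(minus$send[1], minus$sstart[1])), c(101, 220))
})

test_that("native search intervals match the brute-force oracle", {
  set.seed(91)
  for (rep in 1:6) {
    s <- rand_dna(200, 0.5)
    # plant a shared segment so seeds exist, with a mutation to split runs
    q <- rand_dna(150, 0.5)
    frag <- substr(s, 61, 130)
    substr(q, 41, 110) <- frag
    got <- native_search(c(q = q), s, "sub", evalue_max = Inf)
    want <- oracle_search_intervals(q, s)
    got <- got[order(got$qstart, got$sstart), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$qstart, want$qs)
    expect_equal(got$qend, want$qe)
    expect_equal(got$sstart, want$ss)
    expect_equal(got$send, want$se)
  }
})
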