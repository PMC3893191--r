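models <- load_pathway_models()
ALL_KOS <- sort(unique(unlist(lapply(models, function(m) unlist(m$routes)))))

test_that("the packaged pathway fixture covers the 20 amino acids", {
  expect_length(models, 20)
  ess <- names(models)[vapply(models, `[[`, logical(1), "essential")]
  expect_setequal(ess, c("Thr", "Val", "Met", "Leu", "Ile", "Phe", "Lys",
                         "Trp"))
  cond <- names(models)[vapply(models, `[[`, logical(1), "conditional")]
  expect_setequal(cond, c("Arg", "His"))
  expect_true(all(vapply(models, `[[`, integer(1), "n_steps") >= 1))
})

test_that("pathway models survive a write/read round trip", {
  path <- tempfile(fileext = ".tsv")
  write_pathway_models(models, path)
  again <- load_pathway_models(path)
  expect_identical(again, models)
  unlink(path)
})

test_that("malformed pathway files are rejected", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("amino_acid\troute\tstep\tko\tessential", empty)
  expect_error(load_pathway_models(empty), "empty")

  alien <- tempfile(fileext = ".tsv")
  writeLines(c("amino_acid\troute\tstep\tko\tessential",
               "Xyz\t1\t1\tK00001\tno"), alien)
  expect_error(load_pathway_models(alien), "Xyz")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("amino_acid\troute\tstep\tko\tessential",
               "Ala\t1\t1\tK00814\tno",
               "Ala\t1\t1\tK00814\tno"), dup)
  expect_error(load_pathway_models(dup), "duplicate")
  unlink(c(empty, alien, dup))
})

test_that("producibility counts missing steps against the tolerance", {
  lys <- models[["Lys"]]
  full <- producibility(ALL_KOS, lys)
  expect_identical(full$status, "PRODUCIBLE")
  expect_equal(full$n_missing_steps, 0)

  # remove four lysine enzymes: unproducible even with the 2-gap tolerance
  gap4 <- setdiff(ALL_KOS, c("K01714", "K00215", "K01778", "K01586"))
  res4 <- producibility(gap4, lys)
  expect_equal(res4$n_missing_steps, 4)
  expect_identical(res4$status, "NOT_PRODUCIBLE")

  met <- models[["Met"]]
  gap2 <- setdiff(ALL_KOS, c("K00651", "K01739"))
  res2 <- producibility(gap2, met)
  expect_equal(res2$n_missing_steps, 2)
  expect_identical(res2$status, "PRODUCIBLE_WITH_GAPS")
  expect_identical(producibility(gap2, met, tolerance = 0)$status,
                   "NOT_PRODUCIBLE")

  # interchangeable KOs within a step: one of the pair suffices
  asp <- models[["Asp"]]
  expect_identical(producibility("K00813", asp)$status, "PRODUCIBLE")

  expect_error(producibility(ALL_KOS, list(routes = list())), "empty")
})

test_that("producibility is monotone under KO addition", {
  set.seed(41)
  for (rep in 1:20) {
    base <- sample(ALL_KOS, sample(10:50, 1))
    extra <- union(base, sample(ALL_KOS, 10))
    for (aa in sample(names(models), 5)) {
      expect_lte(producibility(extra, models[[aa]])$n_missing_steps,
                 producibility(base, models[[aa]])$n_missing_steps)
    }
  }
})

test_that("complementarity classes partition and reflect designed gaps", {
  set.seed(6)
  ko <- make_ko_tables(models, default_gap_plan())
  comp <- complementarity(ko$host$ko, ko$symbiont$ko, models)
  tab <- comp$table
  expect_equal(nrow(tab), 20)
  expect_equal(sum(comp$summary$overall), 20)
  expect_equal(sum(comp$summary$essential), 8)

  cls <- setNames(tab$class, tab$amino_acid)
  expect_identical(unname(cls["Lys"]), "NEITHER")
  expect_identical(unname(cls["Cys"]), "HOST_ONLY")
  expect_identical(unname(cls["Met"]), "SPLIT")
  expect_true(all(cls[c("Val", "Ile", "Leu", "Phe", "Trp")] ==
                    "SYMBIONT_ONLY"))
  expect_true(all(cls[c("Ala", "Glu", "Gln", "Gly", "Ser", "Pro")] ==
                    "BOTH"))

  # every enzyme in both organisms: everything BOTH
  all_both <- complementarity(ALL_KOS, ALL_KOS, models)
  expect_true(all(all_both$table$class == "BOTH"))

  expect_error(complementarity(ALL_KOS, ALL_KOS, models[-3]),
               models[[3]]$amino_acid)
})

test_that("NEITHER shrinks (never grows) as the tolerance rises", {
  set.seed(47)
  for (rep in 1:10) {
    hk <- sample(ALL_KOS, 40)
    sk <- sample(ALL_KOS, 40)
    prev <- Inf
    for (tol in 0:3) {
      comp <- complementarity(hk, sk, models, tolerance = tol)
      n_neither <- comp$summary$overall[["NEITHER"]]
      expect_lte(n_neither, prev)
      prev <- n_neither
    }
  }
})
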