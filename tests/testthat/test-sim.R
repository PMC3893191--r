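test_that("simulated genomes concentrate around their GC targets", {
  set.seed(42)
  g40 <- make_genome(1e5, 0.40)
  g53 <- make_genome(1e5, 0.53)
  # binomial 3-sigma bound at n = 1e5 is ~0.005 around the target
  expect_gt(gc_fraction(g40), 0.395)
  expect_lt(gc_fraction(g40), 0.405)
  expect_gt(gc_fraction(g53), 0.525)
  expect_lt(gc_fraction(g53), 0.535)

  at_only <- make_genome(100, 0)
  expect_true(grepl("^[AT]+$", at_only))
  expect_error(make_genome(0, 0.5), "positive")
  expect_error(make_genome(-3, 0.5), "positive")
})

test_that("contigs are uniformly placed genome substrings with neutral ids", {
  set.seed(7)
  g <- make_genome(2e4, 0.40)
  one <- make_contigs(g, 1, c(nchar(g), nchar(g)))
  expect_identical(one$seq, g)

  cc <- make_contigs(g, 500, c(200, 2000))
  expect_equal(nrow(cc), 500)
  expect_true(all(vapply(cc$seq, function(s) grepl(s, g, fixed = TRUE),
                         logical(1))))
  expect_lt(abs(mean(cc$gc) - 0.40), 0.01)
  expect_false(any(grepl("host|symbiont", cc$id, ignore.case = TRUE)))

  expect_equal(nrow(make_contigs(g, 0, c(100, 200))), 0)
  expect_error(make_contigs(g, 1, c(100, nchar(g) + 1)), "exceeds")
})

test_that("diploid mutation hits the configured composite rate", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  g <- make_genome(1.1e6, 0.40)
  mut <- mutate_haplotype(g, cfg)
  snp_sites <- sum(mut$variants$kind == "SNP")
  indel_bp <- sum(mut$variants$affected_bp[mut$variants$kind == "INDEL"])
  realized <- (snp_sites + indel_bp) / nchar(g)
  expect_lt(abs(realized - cfg$het_rate) / cfg$het_rate, 0.05)
  # indels are capped at the configured maximum
  expect_true(all(mut$variants$affected_bp[mut$variants$kind == "INDEL"] <=
                    cfg$max_indel))
  # VCF-style representation round-trips onto the reference
  for (i in head(which(mut$variants$kind == "INDEL"), 5)) {
    v <- mut$variants[i, ]
    expect_identical(substr(g, v$pos, v$pos + nchar(v$ref) - 1L), v$ref)
  }
})

test_that("zero heterozygosity gives identical haplotypes and empty truth", {
  cfg <- sim_config(seed = 2, het_rate = 0)
  set.seed(2)
  g <- make_genome(5e4, 0.4)
  mut <- mutate_haplotype(g, cfg)
  expect_identical(mut$alt, g)
  expect_equal(nrow(mut$variants), 0)
})

test_that("read simulation emits the exact engineered duplicate count", {
  cfg <- sim_config(seed = 9, n_host_contigs = 20L, n_symbiont_contigs = 0L,
                    genome_len = 50000L, n_read_pairs = 1000L,
                    duplicate_frac = 0.1)
  set.seed(cfg$seed)
  g <- make_genome(cfg$genome_len, 0.4)
  cc <- make_contigs(g, 20, cfg$contig_len_range)
  rp <- make_read_pairs(cc, cfg)
  expect_equal(sum(rp$pairs$defect == "duplicate"), 100)
  expect_equal(nrow(rp$pairs), 1100)
  expect_false(anyDuplicated(rp$pairs$id) > 0)
})

test_that("excessive heterozygosity is rejected", {
  expect_error(sim_config(het_rate = 0.3), "0.2")
  cfg <- sim_config(seed = 1)
  cfg$het_rate <- 0.3    # bypass constructor validation
  set.seed(1)
  g <- make_genome(1e4, 0.4)
  cc <- make_contigs(g, 3, c(500, 600))
  expect_error(make_read_pairs(cc, cfg), "0.2")
})

test_that("marker tiling overlaps and covers the planted marker", {
  cfg <- sim_config(seed = 4)
  set.seed(4)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0))
  pm <- plant_marker(empty, cfg)
  expect_equal(nchar(pm$marker), 341)
  # ceil((341 - 100)/50) + 1 = 6 tiles minimum
  expect_gte(nrow(pm$reads), 6)
  starts <- pm$tile_starts
  expect_true(all(diff(starts) <= cfg$read_len / 2))
  expect_equal(starts[length(starts)], 341 - cfg$read_len + 1)
  # primers sit on the flanking tiles
  expect_true(grepl(cfg$primer_fwd, pm$marker, fixed = TRUE))
  expect_true(grepl(revcomp(cfg$primer_rev), pm$marker, fixed = TRUE))

  short_cfg <- sim_config(seed = 4, marker_len = 60L)
  expect_error(plant_marker(empty, short_cfg), "shorter")
})

test_that("the same seed reproduces the dataset byte for byte", {
  cfg <- small_config(seed = 31)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_holobiont(cfg), d1)
  write_simulation(simulate_holobiont(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("KO tables carry all enzymes minus the planned deletions", {
  models <- load_pathway_models()
  all_kos <- sort(unique(unlist(lapply(models, function(m)
    unlist(m$routes)))))
  set.seed(1)
  full <- make_ko_tables(models, gap_plan = list())
  expect_setequal(full$host$ko, all_kos)
  expect_setequal(full$symbiont$ko, all_kos)

  set.seed(1)
  ko <- make_ko_tables(models, default_gap_plan())
  expect_false(any(ko$deleted$HOST %in% ko$host$ko))
  expect_false(any(ko$deleted$SYMBIONT %in% ko$symbiont$ko))
  expect_setequal(union(ko$host$ko, ko$deleted$HOST), all_kos)

  expect_error(
    make_ko_tables(models, list(Lys = list(HOST = "K99999"))), "K99999")
})
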