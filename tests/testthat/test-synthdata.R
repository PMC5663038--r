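test_that("configuration validates probabilities and demands a seed", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, theta = 1.5))
  cfg <- synthetic_config(seed = 1)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$n_orthologs, 13515L)
  expect_equal(cfg$promoter_length, 500L)
  expect_equal(cfg$n_tissues, 5L)
})

test_that("generators are deterministic under a fixed seed and leave the RNG alone", {
  cfg <- synthetic_config(seed = 7, n_orthologs = 300L)
  g1 <- generate_ortholog_table(cfg)
  g2 <- generate_ortholog_table(cfg)
  expect_identical(g1, g2)
  p1 <- generate_promoters(cfg, rep(c("plastic", "constrained"), 5))
  p2 <- generate_promoters(cfg, rep(c("plastic", "constrained"), 5))
  expect_identical(p1, p2)
  cfgB <- synthetic_config(seed = 8, n_orthologs = 300L)
  expect_false(identical(generate_ortholog_table(cfgB), g1))

  set.seed(123); before <- .Random.seed
  invisible(generate_ortholog_table(cfg))
  expect_identical(.Random.seed, before)
})

test_that("degenerate regimes: theta=1, rho=1 gives all-constrained marking", {
  cfg <- synthetic_config(seed = 2, n_orthologs = 200L, theta = 1, rho = 1)
  g <- generate_ortholog_table(cfg)
  cls <- mark_class(g$records)
  expect_true(all(cls == "constrained"))
  pat <- classify_pattern(g$records)
  expect_true(all(pat$n_marked == 3L))
})

test_that("theta=0 marking is independent across species: matches the null", {
  cfg <- synthetic_config(seed = 31, n_orthologs = 50000L, theta = 0,
                          switch_rate = 0.25)
  g <- generate_ortholog_table(cfg)
  tab <- tabulate_patterns(g$records)
  # the unconditional-null variant is the one independence reproduces
  nf <- expected_pattern_fractions(tab, base = "all")
  n <- sum(tab$count)
  sizes <- lengths(strsplit(as.character(tab$pattern), "+", fixed = TRUE)) *
    (tab$pattern != "none")
  obs_single <- sum(tab$count[sizes == 1]) / n
  obs_triple <- sum(tab$count[sizes == 3]) / n
  mc <- 3 / sqrt(n)  # generous Monte-Carlo band
  expect_lt(abs(obs_single - nf$expected_single), mc)
  expect_lt(abs(obs_triple - nf$expected_triple), mc)
  expect_equal(unname(nf$marginals), rep(0.25, 3), tolerance = 0.02)
  expect_equal(sum(nf$expected), 1, tolerance = 1e-12)
})

test_that("the deterministic fixture reproduces the published counts exactly", {
  rec <- table1_marking_table()
  expect_equal(nrow(rec), 13515L)
  t27 <- tabulate_patterns(rec, "H3K27me3")
  expect_equal(sum(t27$count), 13515L)
  expect_identical(table1_marking_table(), rec)  # no hidden randomness
})

test_that("promoter generator: AT boost shifts 4-mer Z-scores, delta=0 is null", {
  cfg <- synthetic_config(seed = 41)
  labels <- rep(c("constrained", "plastic"), each = 1000)
  prom <- generate_promoters(cfg, labels)
  z <- fourmer_zscores(prom[labels == "constrained"],
                       prom[labels == "plastic"])
  expect_gt(z$z[z$kmer == "AAAA"], 2)
  expect_gt(z$z[z$kmer == "ATAT"], 2)
  expect_lt(z$z[z$kmer == "GCGC"], 0)

  cfg0 <- synthetic_config(seed = 42, at_boost = 0)
  prom0 <- generate_promoters(cfg0, labels)
  z0 <- fourmer_zscores(prom0[labels == "constrained"],
                        prom0[labels == "plastic"])
  expect_lt(max(abs(z0$z)), 4.5)  # null: no systematic signal
  expect_lt(mean(abs(z0$z) > 2), 0.12)
})

test_that("expression generator: Dirichlet concentration drives tissue entropy", {
  labels <- rep(c("constrained", "plastic"), each = 300)
  cfg <- synthetic_config(seed = 52)
  ex <- generate_expression(cfg, labels)
  h <- apply(ex, 1, tissue_entropy)
  expect_lt(mean(h[labels == "constrained"]), mean(h[labels == "plastic"]))

  # limits: alpha -> 0 gives entropy -> 0; large alpha approaches log2(5)
  lo <- generate_expression(synthetic_config(seed = 53,
                                             alpha_constrained = 0.01),
                            rep("constrained", 200))
  hi <- generate_expression(synthetic_config(seed = 54,
                                             alpha_plastic = 500),
                            rep("plastic", 200))
  expect_lt(mean(apply(lo, 1, tissue_entropy)), 0.2)
  expect_gt(mean(apply(hi, 1, tissue_entropy)), log2(5) - 0.05)
})

test_that("block generator injects detectable enrichment (power > 0.8)", {
  cfg <- synthetic_config(seed = 61, enrich_factor = 3, block_size = 30L,
                          frac_enriched = 0.15)
  n <- 6000
  set.seed(61)
  cls <- setNames(sample(c("plastic", "constrained", "unmarked"), n, TRUE,
                         prob = c(0.14, 0.13, 0.73)),
                  sprintf("gene%05d", 1:n))
  blk <- generate_blocks(cfg, cls)
  expect_setequal(blk$blocks$gene_id, names(cls))
  res <- block_binomial_enrichment(blk$blocks, cls, "constrained")
  truth <- merge(res, blk$categories, by = "block_id")
  power <- mean(truth$enriched[truth$category == "constrained_enriched"])
  fpr <- mean(truth$enriched[truth$category == "not_enriched"])
  expect_gt(power, 0.8)
  expect_lt(fpr, 0.15)
})

test_that("a full dataset round-trips through the standard formats with a manifest", {
  dir <- file.path(tempdir(), "synthds")
  cfg <- synthetic_config(seed = 71, n_orthologs = 400L)
  paths <- write_synthetic_dataset(cfg, dir, n_bins = 30L)
  rec <- read_marking_table(paths$marking)
  expect_equal(nrow(rec), 400L)
  prom <- Biostrings::readDNAStringSet(paths$promoters)
  expect_length(prom, 400L)
  expect_equal(unique(Biostrings::width(prom)), 500L)
  expr <- read_expression_matrix(paths$expression)
  expect_equal(dim(expr), c(400L, 5L))
  blocks <- read_synteny_blocks(paths$blocks)
  expect_equal(length(unique(blocks$gene_id)), 400L)
  cm <- read_contact_matrix(paths$contacts)
  expect_equal(nrow(cm$scores), 30L)
  expect_equal(cm$scores, t(cm$scores))
  man <- jsonlite::read_json(paths$manifest)
  expect_equal(man$seed, 71L)
  expect_equal(man$at_boost, cfg$at_boost)

  # byte-level determinism of the emitted files
  dir2 <- file.path(tempdir(), "synthds2")
  paths2 <- write_synthetic_dataset(cfg, dir2, n_bins = 30L)
  for (nm in c("marking", "promoters", "expression", "blocks", "contacts"))
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
})
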