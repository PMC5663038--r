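test_that("pattern classification reflects flags and rejects NA", {
  m <- rbind(c(1, 1, 1), c(0, 0, 1), c(1, 0, 1), c(0, 0, 0))
  pat <- classify_pattern(toy_marking_table(m), "H3K27me3")
  expect_equal(as.character(pat$pattern),
               c("Ath+Aly+Aal", "Aal", "Ath+Aal", "none"))
  expect_equal(pat$n_marked, c(3L, 1L, 2L, 0L))
  expect_equal(pat$concordant, c(TRUE, FALSE, TRUE, FALSE))

  tab <- table1_marking_table()
  tab$H3K27me3_Aal[1] <- NA
  tab$H3K4me3_Aal[1] <- NA
  tab$gene_Aal[1] <- NA
  expect_error(classify_pattern(tab, "H3K27me3"), "single-copy")
})

test_that("plastic/constrained and lineage-specific/concordant collapse rules", {
  expect_equal(classify_h3k27(c("Ath+Aly", "Aal", "Aly+Aal", "Ath+Aal",
                                "Ath+Aly+Aal", "Ath", "none")),
               c("plastic", "plastic", "constrained", "constrained",
                 "constrained", "plastic", "unmarked"))
  expect_equal(classify_h3k4(c("Ath+Aly", "Aal", "Ath+Aly+Aal", "none")),
               c("concordant", "lineage_specific", "concordant", "unmarked"))
})

test_that("classifier is symmetric in the sister pair but not with the outermost species", {
  pats <- setdiff(epiconcord:::pattern_levels(species_config()), "none")
  swap <- function(k, a, b) {
    s <- strsplit(k, "+", fixed = TRUE)[[1]]
    s[s == a] <- "tmp"; s[s == b] <- a; s[s == "tmp"] <- b
    paste(intersect(c("Ath", "Aly", "Aal"), s), collapse = "+")
  }
  for (k in pats) {
    expect_equal(classify_h3k27(swap(k, "Ath", "Aly")), classify_h3k27(k))
  }
  swapped_out <- vapply(pats, swap, character(1), a = "Aly", b = "Aal")
  expect_false(all(classify_h3k27(swapped_out) == classify_h3k27(pats)))
})

test_that("tabulation on the fixture reproduces the published table cell-for-cell", {
  rec <- table1_marking_table()
  t27 <- tabulate_patterns(rec, "H3K27me3")
  expect_equal(t27$count, c(1464L, 512L, 97L, 197L, 775L, 327L, 301L, 9842L))
  expect_equal(t27$outgroup_count, c(384L, 68L, 10L, 31L, 121L, 44L, 46L, 0L))
  t4 <- tabulate_patterns(rec, "H3K4me3")
  expect_equal(t4$count, c(10010L, 505L, 280L, 188L, 201L, 291L, 289L, 1751L))
  expect_equal(sum(t27$count), 13515L)

  empty <- tabulate_patterns(rec[0, ], "H3K27me3")
  expect_equal(empty$count, rep(0L, 8))
})

test_that("class partition: every record in exactly one class, fixture counts match", {
  rec <- table1_marking_table()
  cls <- mark_class(rec, "H3K27me3")
  expect_equal(length(cls), 13515L)
  expect_true(all(cls %in% c("plastic", "constrained", "unmarked")))
  cc <- table(cls)
  expect_equal(as.integer(cc[c("constrained", "plastic", "unmarked")]),
               c(1758L, 1915L, 9842L))
})

test_that("concordance summary handles marked, unmarked and degenerate tables", {
  rec <- table1_marking_table()
  s <- concordance_summary(tabulate_patterns(rec, "H3K27me3"))
  expect_equal(s$n_marked_any, 3673L)
  expect_equal(s$frac_marked_any, 3673 / 13515)
  expect_equal(s$frac_concordant, 2270 / 3673)
  expect_equal(s$frac_sister_pair, 512 / 806)
  s4 <- concordance_summary(tabulate_patterns(rec, "H3K4me3"))
  expect_equal(s4$frac_marked_any, 11764 / 13515)
  expect_equal(s4$frac_concordant, (10010 + 505 + 280 + 188) / 11764)

  all0 <- toy_marking_table(matrix(0L, 4, 3))
  s0 <- concordance_summary(tabulate_patterns(all0, "H3K27me3"))
  expect_equal(s0$frac_marked_any, 0)
  expect_true(is.na(s0$frac_concordant) && is.na(s0$frac_sister_pair))
})

test_that("independence null matches direct 8-pattern enumeration", {
  # oracle: enumerate all 2^3 marking patterns from the marginals
  enum_null <- function(p) {
    pats <- expand.grid(0:1, 0:1, 0:1)
    prob <- apply(pats, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
    cond <- prob[rowSums(pats) > 0] / (1 - prob[rowSums(pats) == 0])
    sizes <- rowSums(pats)[rowSums(pats) > 0]
    c(single = sum(cond[sizes == 1]), triple = sum(cond[sizes == 3]),
      total = sum(cond))
  }
  nf <- expected_pattern_fractions(tabulate_patterns(table1_marking_table(),
                                                     "H3K27me3"))
  oracle <- enum_null(nf$marginals)
  expect_equal(nf$expected_single, unname(oracle["single"]), tolerance = 1e-12)
  expect_equal(nf$expected_triple, unname(oracle["triple"]), tolerance = 1e-12)
  expect_equal(sum(nf$expected), 1, tolerance = 1e-12)
  # printed values
  expect_equal(round(100 * nf$expected_single), 22)
  expect_equal(round(100 * nf$expected_triple), 30)

  # half-half marginals: closed form 3 * 0.125 / 0.875
  m <- matrix(0L, 8, 3)
  m[1:7, ] <- t(sapply(1:7, function(i) as.integer(intToBits(i)[1:3])))
  tab <- tabulate_patterns(toy_marking_table(rbind(m[1:7, ], m[1:7, ])))
  nf2 <- expected_pattern_fractions(tab)
  expect_equal(unname(nf2$marginals), rep(4 / 7, 3))
  expect_error(expected_pattern_fractions(
    tabulate_patterns(toy_marking_table(matrix(0L, 3, 3)))), "no marked")
})

test_that("cross-clade fractions and empty categories", {
  tab <- tabulate_patterns(table1_marking_table(), "H3K27me3")
  expect_equal(cross_clade_fraction(tab, "triple"), 384 / 1464)
  expect_equal(cross_clade_fraction(tab, "plastic"), 279 / 1915)
  expect_equal(cross_clade_fraction(tab, "constrained"), (384 + 10 + 31) / 1758)
  empty <- tabulate_patterns(toy_marking_table(matrix(0L, 2, 3)))
  expect_true(is.na(cross_clade_fraction(empty, "triple")))
})

test_that("marking frequency is NA-aware", {
  m <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 0, 0), c(0, 0, 0),
             matrix(0L, 5, 3))
  rec <- toy_marking_table(m)
  expect_equal(marking_frequency(rec, "Ath"), 0.3)
  rec$gene_Aal <- NA
  rec$H3K27me3_Aal <- NA_integer_
  rec$H3K4me3_Aal <- NA_integer_
  expect_true(is.na(marking_frequency(rec, "Aal")))
  expect_error(marking_frequency(rec, "Zzz"), "unknown species")
})

test_that("species restriction fraction matches generator truth and edge rules", {
  rec <- toy_marking_table(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 0)))
  dup <- list("Ath", "Ath", "Ath")
  # record 3 unmarked: excluded; record 1 restricted, record 2 not
  expect_equal(species_restriction_fraction(rec, dup), 0.5)

  set.seed(11)
  n <- 2000
  restricted <- runif(n) < 0.8
  flags <- t(sapply(restricted, function(r)
    if (r) c(1L, 0L, 0L) else c(1L, sample(0:1, 1), 1L)))
  flags[!restricted & flags[, 3] == 0, 3] <- 1L
  frac <- species_restriction_fraction(toy_marking_table(flags),
                                       rep(list("Ath"), n))
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})
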