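test_that("two-way ANOVA: exact zero effects, oracle agreement, contracts", {
  # equal cell means in a balanced design: both SS exactly 0, F = 0
  a <- rep(c("x", "y"), each = 8)
  b <- rep(c("u", "v"), 8)
  y <- rep(c(0, 0, 2, 2), 4)  # every a x b cell holds {0, 2}: cell means 1
  res <- twoway_anova(y, a, b)
  expect_equal(res$ss[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(res$f[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(res$omega_sq[1:2], c(0, 0))

  set.seed(4)
  # balanced 2x2 with additive effects
  y2 <- 2 + (a == "y") * 1.5 + (b == "v") * -0.7 + rnorm(16)
  res2 <- twoway_anova(y2, a, b)
  or <- anova_type2_oracle(y2, a, b)
  expect_equal(res2$ss[1], or$ss_a, tolerance = 1e-8)
  expect_equal(res2$ss[2], or$ss_b, tolerance = 1e-8)
  expect_equal(res2$ss[3], or$rss, tolerance = 1e-8)

  # unbalanced groups (the motivating case for Type II)
  au <- c(rep("x", 30), rep("y", 10))
  bu <- sample(c("u", "v"), 40, replace = TRUE)
  yu <- 1 + (au == "y") * 0.8 + (bu == "v") * 0.3 + rnorm(40)
  ru <- twoway_anova(yu, au, bu)
  oru <- anova_type2_oracle(yu, au, bu)
  expect_equal(ru$ss[1], oru$ss_a, tolerance = 1e-8)
  expect_equal(ru$ss[2], oru$ss_b, tolerance = 1e-8)

  # omega squared formula and clipping
  ms_err <- ru$ms[ru$effect == "Residuals"]
  ss_tot <- sum((yu - mean(yu))^2)
  expect_equal(ru$omega_sq[1],
               max(0, (ru$ss[1] - ru$df[1] * ms_err) / (ss_tot + ms_err)))

  expect_error(twoway_anova(yu, rep("x", 40), bu), "two observed levels")
  # interaction with an empty cell
  ae <- c("x", "x", "y", "y"); be <- c("u", "u", "u", "v")
  expect_error(twoway_anova(rnorm(4), ae, be, interaction = TRUE),
               "empty cell")
})

test_that("balanced SS decomposition sums to total", {
  set.seed(12)
  a <- rep(c("x", "y"), each = 20)
  b <- rep(rep(c("u", "v"), each = 10), 2)
  y <- rnorm(40) + (a == "y") + 0.5 * (b == "v")
  r <- twoway_anova(y, a, b, interaction = TRUE)
  expect_equal(sum(r$ss), sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("exact binomial enrichment p-values match enumeration to 1e-12", {
  expect_equal(binom_upper_p(5, 10, 0.5), 638 / 1024, tolerance = 1e-15)
  expect_equal(binom_upper_p(10, 10, 0.1), 0.1^10, tolerance = 1e-9)
  expect_equal(binom_upper_p(0, 10, 0.3), 1)

  set.seed(2)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    oracle <- sum(dbinom(k:n, n, p0))  # enumeration of point masses
    expect_equal(binom_upper_p(k, n, p0), oracle, tolerance = 1e-12)
  }
})

test_that("block enrichment uses the over-blocks average rate and flags p < alpha", {
  blocks <- data.frame(
    block_id = rep(c("b1", "b2", "b3"), c(10, 10, 5)),
    gene_id = sprintf("g%02d", 1:25))
  cls <- setNames(rep("other", 25), blocks$gene_id)
  cls[c(1:8, 11)] <- "constrained"  # b1: 8/10, b2: 1/10, b3: 0/5
  res <- block_binomial_enrichment(blocks, cls, "constrained")
  p0 <- mean(c(8 / 10, 1 / 10, 0 / 5))
  expect_equal(unique(res$p0), p0)
  expect_equal(res$p_value,
               sapply(seq_len(3), function(i)
                 sum(dbinom(res$n_class[i]:res$n_genes[i], res$n_genes[i],
                            p0))),
               tolerance = 1e-12)
  expect_equal(res$enriched, res$p_value < 0.05)

  blocks0 <- rbind(blocks, data.frame(block_id = "b4", gene_id = "zzz"))
  cls2 <- c(cls, zzz = "other")
  expect_silent(block_binomial_enrichment(blocks0, cls2, "constrained"))
  # BH option changes only the enriched flag, never the raw p
  rbh <- block_binomial_enrichment(blocks, cls, "constrained", adjust = "BH")
  expect_equal(rbh$p_value, res$p_value)
})

test_that("Fisher enumeration: edge cases, transpose invariance, oracle agreement", {
  expect_equal(fisher_cooccurrence(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  expect_equal(fisher_cooccurrence(matrix(c(0, 0, 3, 5), 2))$p_value, 1)

  t1 <- matrix(c(10, 30, 90, 70), 2)
  expect_equal(fisher_cooccurrence(t1)$p_value,
               fisher.test(t1)$p.value, tolerance = 1e-12)
  expect_equal(fisher_cooccurrence(t1)$p_value,
               fisher_cooccurrence(t(t1))$p_value, tolerance = 1e-15)

  set.seed(6)
  for (i in 1:100) {
    m <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_cooccurrence(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(fisher_cooccurrence(matrix(c(4, 1, 2, 8), 2))$odds_ratio,
               (4 * 8) / (1 * 2))
})

test_that("ohnolog pair concordance: expected squares, constructed excess, contracts", {
  frac <- c(plastic = 1915 / 13515, constrained = 1758 / 13515)
  pairs <- data.frame(class_a = c("plastic", "unmarked"),
                      class_b = c("plastic", "unmarked"))
  r <- ohnolog_pair_concordance(pairs, frac)
  expect_equal(round(100 * r$expected_both_plastic), 2)
  expect_equal(round(100 * r$expected_both_constrained), 2)
  expect_equal(r$observed_both_plastic, 0.5)

  # all pairs identical-class: observed far above expected, chi-square large
  set.seed(10)
  lab <- sample(c("plastic", "constrained", "unmarked"), 500, replace = TRUE,
                prob = c(frac, 1 - sum(frac)))
  same <- data.frame(class_a = lab, class_b = lab)
  rs <- ohnolog_pair_concordance(same, frac)
  expect_equal(rs$observed_both_plastic, mean(lab == "plastic"))
  expect_gt(rs$chi_square, qchisq(0.999, 2))
  expect_lt(rs$p_value, 0.001)

  expect_error(ohnolog_pair_concordance(pairs[0, ], frac), "no ohnolog")
})
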