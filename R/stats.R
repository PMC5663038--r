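# Inferential statistics built around the marking classifications: two-way
# ANOVA with omega-squared effect sizes, per-synteny-block exact binomial
# enrichment, Fisher exact co-occurrence tests, and ohnolog-pair class
# concordance.

#' Two-way ANOVA with omega-squared effect sizes
#'
#' Fits sequence similarity (or any response) against two categorical
#' factors — typically concordance of marking and uniqueness of marking
#' (single- vs co-marking) — using Type II sums of squares, which are
#' appropriate for the unbalanced group sizes that marking classes produce.
#' Effect size per factor is omega squared,
#'   w2 = (SS_eff - df_eff * MS_err) / (SS_total + MS_err),
#' clipped at 0; it estimates the share of response variance attributable to
#' the factor.
#'
#' @param response numeric response vector.
#' @param factor_a,factor_b factors (coerced); >= 2 levels each.
#' @param interaction include the A:B interaction (default FALSE; requires
#'   every cell non-empty).
#' @return data.frame with one row per effect (A, B, optional A:B,
#'   Residuals): `ss`, `df`, `ms`, `f`, `p`, `omega_sq` (NA for residuals).
#' @export
twoway_anova <- function(response, factor_a, factor_b, interaction = FALSE) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(response) == length(a), length(a) == length(b))
  if (nlevels(droplevels(a)) < 2L || nlevels(droplevels(b)) < 2L)
    stop("each factor needs at least two observed levels")
  a <- droplevels(a); b <- droplevels(b)
  if (interaction && any(table(a, b) == 0L))
    stop("empty cell: interaction not estimable")
  df <- data.frame(y = response, a = a, b = b)
  rss <- function(form) sum(stats::resid(stats::lm(form, data = df))^2)
  full_form <- if (interaction) y ~ a + b + a:b else y ~ a + b
  fit_full <- stats::lm(full_form, data = df)
  rss_full <- sum(stats::resid(fit_full)^2)
  # Type II: each main effect adjusted for the other main effect (not for
  # the interaction); the interaction adjusted for both main effects.
  rss_ab <- rss(y ~ a + b)
  ss_a <- rss(y ~ b) - rss_ab
  ss_b <- rss(y ~ a) - rss_ab
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  effects <- list(A = c(ss_a, df_a), B = c(ss_b, df_b))
  if (interaction) {
    ss_int <- rss_ab - rss_full
    effects[["A:B"]] <- c(ss_int, df_a * df_b)
  }
  df_err <- fit_full$df.residual
  ms_err <- rss_full / df_err
  ss_total <- sum((response - mean(response))^2)
  rows <- lapply(names(effects), function(nm) {
    ss <- max(0, effects[[nm]][1]); dfe <- effects[[nm]][2]
    ms <- ss / dfe
    fval <- ms / ms_err
    w2 <- (ss - dfe * ms_err) / (ss_total + ms_err)
    data.frame(effect = nm, ss = ss, df = dfe, ms = ms, f = fval,
               p = stats::pf(fval, dfe, df_err, lower.tail = FALSE),
               omega_sq = max(0, w2), stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <-
    data.frame(effect = "Residuals", ss = rss_full, df = df_err,
               ms = ms_err, f = NA_real_, p = NA_real_,
               omega_sq = NA_real_, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Exact one-sided binomial p-value (upper tail)
#'
#' P(X >= k) for X ~ Binomial(n, p0), as an exact sum of point masses.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 success probability under the null.
#' @return p-value.
#' @export
binom_upper_p <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (k == 0L) return(1)
  stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
}

#' Per-synteny-block binomial enrichment test
#'
#' For every synteny block, tests whether the proportion of genes of a given
#' marking class exceeds expectation: successes = genes of the class in the
#' block, trials = genes in the block, expected probability p0 = class
#' proportion averaged over all synteny blocks (unless supplied).  One-sided
#' upper-tail exact binomial p; a block is called enriched at p < alpha
#' (raw p-values by default, mirroring the published procedure; set
#' `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param blocks data.frame with `block_id`, `gene_id`.
#' @param gene_classes named character vector: class label per gene_id.
#' @param class_label class tested for enrichment (e.g. `"constrained"`).
#' @param p0 expected success probability; default: mean over blocks of the
#'   per-block class proportion.
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with block_id, n_genes, n_class, p0, p_value,
#'   enriched. Blocks with 0 genes are skipped with a warning.
#' @export
block_binomial_enrichment <- function(blocks, gene_classes, class_label,
                                      p0 = NULL, alpha = 0.05,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ids <- unique(blocks$block_id)
  per_block <- lapply(ids, function(bid) {
    genes <- blocks$gene_id[blocks$block_id == bid]
    cls <- gene_classes[genes]
    c(n = length(genes), k = sum(cls == class_label, na.rm = TRUE))
  })
  n <- vapply(per_block, `[[`, numeric(1), "n")
  k <- vapply(per_block, `[[`, numeric(1), "k")
  empty <- n == 0
  if (any(empty)) {
    warning(sum(empty), " empty block(s) skipped")
    ids <- ids[!empty]; n <- n[!empty]; k <- k[!empty]
  }
  if (is.null(p0)) p0 <- mean(k / n)
  stopifnot(p0 > 0, p0 < 1)
  p <- mapply(binom_upper_p, k, n, MoreArgs = list(p0 = p0))
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.frame(block_id = ids, n_genes = as.integer(n),
             n_class = as.integer(k), p0 = p0, p_value = p,
             enriched = padj < alpha, stringsAsFactors = FALSE)
}

#' Fisher exact test on a 2x2 table (two-sided, by enumeration)
#'
#' Enumerates all tables with the observed margins; the two-sided p-value
#' sums the hypergeometric probabilities of tables no more probable than the
#' observed one (with the conventional (1 + 1e-7) tolerance on "no more
#' probable").  The sample odds ratio is reported.
#'
#' @param table2x2 2x2 matrix of non-negative counts.
#' @return list with `odds_ratio`, `p_value`.
#' @export
fisher_cooccurrence <- function(table2x2) {
  m <- as.matrix(table2x2)
  stopifnot(all(dim(m) == 2L), all(m >= 0))
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    p <- 1
  } else {
    support <- max(0, r1 + c1 - N):min(r1, c1)
    dens <- stats::dhyper(support, c1, N - c1, r1)
    p_obs <- stats::dhyper(a, c1, N - c1, r1)
    p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = unname(or), p_value = unname(p))
}

#' Class concordance of ohnolog pairs
#'
#' Duplicate pairs retained from whole-genome duplication are tested for
#' belonging to the same marking class more often than chance.  Observed:
#' fraction of pairs with both members plastic (resp. constrained).
#' Expected under independence: the squared class fraction in the base
#' population (all single-copy orthologs by default).  A chi-square
#' goodness-of-fit over {both-plastic, both-constrained, other} is reported.
#'
#' @param pair_classes data.frame with columns `class_a`, `class_b` (labels
#'   of the two pair members).
#' @param class_fractions named vector with elements `plastic` and
#'   `constrained`: class fractions in the base population.
#' @return list with n_pairs, observed/expected both-plastic and
#'   both-constrained fractions, chi_square, df, p_value.
#' @export
ohnolog_pair_concordance <- function(pair_classes, class_fractions) {
  n <- nrow(pair_classes)
  if (n == 0L) stop("no ohnolog pairs supplied")
  both <- function(lbl) mean(pair_classes$class_a == lbl &
                             pair_classes$class_b == lbl)
  obs_p <- both("plastic"); obs_c <- both("constrained")
  exp_p <- unname(class_fractions["plastic"]^2)
  exp_c <- unname(class_fractions["constrained"]^2)
  obs_counts <- c(obs_p, obs_c, 1 - obs_p - obs_c) * n
  exp_probs <- c(exp_p, exp_c, 1 - exp_p - exp_c)
  chi <- sum((obs_counts - n * exp_probs)^2 / (n * exp_probs))
  list(n_pairs = n,
       observed_both_plastic = obs_p, expected_both_plastic = exp_p,
       observed_both_constrained = obs_c, expected_both_constrained = exp_c,
       chi_square = chi, df = 2L,
       p_value = stats::pchisq(chi, 2L, lower.tail = FALSE))
}
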