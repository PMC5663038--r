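# Independent oracles used by the unit and acceptance tests. These never
# call the package code paths they check.

# --- F84 numeric oracle ----------------------------------------------------
# Solves the F84 moment equations numerically: builds the F84 rate matrix
# with transition-boost parameter kpar, computes expected transition /
# transversion proportions at time t via the matrix exponential (spectral
# form through the pi-symmetrized generator), and finds (kpar, t) matching
# the observed P and Q. The distance is t times the mean substitution rate.

f84_rate_matrix <- function(pi, kpar) {
  b <- c("A", "C", "G", "T")
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  for (i in b) for (j in b) if (i != j) {
    boost <- if (ts[[i]] == j) {
      grp <- if (j %in% c("A", "G")) piR else piY
      1 + kpar / grp
    } else 1
    Q[i, j] <- pi[[j]] * boost
  }
  diag(Q) <- -rowSums(Q)
  Q
}

f84_expected_PQ <- function(pi, kpar, t) {
  b <- c("A", "C", "G", "T")
  Q <- f84_rate_matrix(pi, kpar)
  d <- sqrt(pi[b])
  S <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  M <- diag(1 / d) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(d)
  dimnames(M) <- list(b, b)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  P <- sum(vapply(b, function(i) pi[[i]] * M[i, ts[[i]]], numeric(1)))
  tv <- function(i) setdiff(b, c(i, ts[[i]]))
  Qp <- sum(vapply(b, function(i) pi[[i]] * sum(M[i, tv(i)]), numeric(1)))
  c(P = P, Q = Qp)
}

f84_numeric_distance <- function(P_obs, Q_obs, pi) {
  # nested root-solve: E[Q] is increasing in t for fixed kpar, so invert it
  # by uniroot; then solve E[P](kpar, t(kpar)) = P_obs over kpar.
  t_for <- function(kpar) {
    uniroot(function(t) f84_expected_PQ(pi, kpar, t)["Q"] - Q_obs,
            c(1e-9, 100), tol = 1e-14)$root
  }
  h <- function(kpar) {
    f84_expected_PQ(pi, kpar, t_for(kpar))["P"] - P_obs
  }
  # kpar may be negative (transition deficit) down to -min(piR, piY),
  # where the transition-boost term would make rates negative
  klo <- -0.99 * min(pi["A"] + pi["G"], pi["C"] + pi["T"])
  kpar <- uniroot(h, c(klo, 100), tol = 1e-13)$root
  t <- t_for(kpar)
  e <- f84_expected_PQ(pi, kpar, t)
  stopifnot(abs(e["P"] - P_obs) < 1e-9, abs(e["Q"] - Q_obs) < 1e-9)
  mu <- -sum(pi * diag(f84_rate_matrix(pi, kpar)))
  unname(t * mu)
}

# --- ANOVA design-matrix projection oracle ---------------------------------
# RSS of a least-squares fit computed from the explicit normal-equations
# projection y' (I - X (X'X)^- X') y; Type II SS by model differencing.

proj_rss <- function(y, X) {
  XtX <- crossprod(X)
  H <- X %*% MASS_ginv(XtX) %*% t(X)
  r <- y - H %*% y
  sum(r^2)
}

# small local pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

anova_type2_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  Xa <- model.matrix(~a); Xb <- model.matrix(~b); Xab <- model.matrix(~a + b)
  rss_ab <- proj_rss(y, Xab)
  list(ss_a = proj_rss(y, Xb) - rss_ab,
       ss_b = proj_rss(y, Xa) - rss_ab,
       rss = rss_ab)
}

# --- misc ------------------------------------------------------------------

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# mutate a sequence: each site changes w.p. rate; transitions twice as
# likely as each transversion
mutate_dna <- function(seq, rate) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  x <- strsplit(seq, "")[[1]]
  hit <- runif(length(x)) < rate
  x[hit] <- vapply(x[hit], function(b) {
    tv <- setdiff(c("A", "C", "G", "T"), c(b, ts[[b]]))
    sample(c(ts[[b]], tv), 1L, prob = c(0.5, 0.25, 0.25))
  }, character(1))
  paste(x, collapse = "")
}

# tiny valid marking table built directly (bypasses the generators)
toy_marking_table <- function(flags27, flags4 = NULL, outgroup = NULL) {
  n <- nrow(flags27)
  if (is.null(flags4)) flags4 <- matrix(1L, n, 3)
  sp <- c("Ath", "Aly", "Aal")
  df <- data.frame(protogene_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (s in sp) df[[paste0("gene_", s)]] <- sprintf("%s_%03d", s, seq_len(n))
  for (j in 1:3) df[[paste0("H3K27me3_", sp[j])]] <- as.integer(flags27[, j])
  for (j in 1:3) df[[paste0("H3K4me3_", sp[j])]] <- as.integer(flags4[, j])
  if (!is.null(outgroup)) df$outgroup_H3K27me3 <- as.integer(outgroup)
  validate_marking_table(df)
}
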