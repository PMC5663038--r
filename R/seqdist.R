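# Alignment-free k-mer sequence comparison and closed-form F84 pairwise
# distance on supplied alignments.
#
# Promoters (non-coding) are compared without alignment: overlapping k-mer
# frequency profiles are built per sequence, high-frequency k-mers (defined
# on a reference collection) are removed, and profiles are compared by
# Jensen-Shannon divergence (base 2, bounded [0,1]) or Pearson distance
# (1 - r, bounded [0,2]). Coding sequences are compared on supplied pairwise
# alignments with the F84 substitution model, which distinguishes
# transitions from transversions under unequal base frequencies and admits a
# closed-form distance.

#' Default k-mer length for a sequence length
#'
#' The minimum k that still allows a full vocabulary for a sequence of
#' length N over an alphabet of c characters: k = floor(log_c(N)).  For
#' 500-bp promoters over DNA this gives k = 4; for ~1.2-kb coding sequences
#' k = 5.
#'
#' @param N sequence length (bp).
#' @param c alphabet size (4 for DNA).
#' @return integer k >= 1.
#' @export
select_k <- function(N, c = 4L) {
  stopifnot(N >= c, c >= 2)
  max(1L, as.integer(floor(log(N) / log(c) + 1e-9)))
}

all_kmers <- function(k, alphabet = c("A", "C", "G", "T")) {
  if (k == 1L) return(alphabet)
  do.call(paste0, rev(expand.grid(rep(list(alphabet), k),
                                  stringsAsFactors = FALSE)))
}

#' Count overlapping k-mers in a DNA sequence
#'
#' Windows containing `N` (or any non-ACGT character) are skipped, so counts
#' are deterministic.  Returns raw counts over the full 4^k vocabulary.
#'
#' @param seq character scalar or `Biostrings::DNAString`.
#' @param k k-mer length.
#' @return named integer vector of length 4^k.
#' @export
kmer_counts <- function(seq, k) {
  s <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  if (length(s) < k) stop("sequence shorter than k")
  # oligonucleotideFrequency ignores windows with ambiguity codes (counts
  # only exact ACGT words), which matches the skip-N contract
  cnt <- Biostrings::oligonucleotideFrequency(s, width = k, step = 1L)
  cnt[all_kmers(k)]
}

#' Build a normalized k-mer frequency profile
#'
#' @param seq DNA sequence.
#' @param k k-mer length (default from [select_k()]).
#' @param remove character vector of k-mers to drop before renormalizing
#'   (typically from [high_frequency_kmers()] computed on the reference
#'   promoter collection); may be empty.
#' @return object of class `kmer_profile`: list with `k`, `frequencies`
#'   (length 4^k, zero at removed k-mers, summing to 1 over retained ones),
#'   `removed_kmers`.
#' @export
kmer_profile <- function(seq, k = NULL, remove = character(0)) {
  s <- if (inherits(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  if (is.null(k)) k <- select_k(length(s))
  cnt <- kmer_counts(s, k)
  cnt[names(cnt) %in% remove] <- 0L
  tot <- sum(cnt)
  freq <- if (tot > 0) cnt / tot else cnt * 0
  structure(list(k = k, frequencies = freq,
                 removed_kmers = intersect(names(cnt), remove)),
            class = "kmer_profile")
}

#' High-frequency k-mers of a reference collection
#'
#' K-mers whose pooled frequency across the collection exceeds the given
#' quantile are flagged for removal (over-abundant words dominate profile
#' correlations and blunt sensitivity).  The threshold is computed once on
#' the reference collection and applied to every profile, keeping the
#' filtering deterministic and collection-level.
#'
#' @param seqs character vector (or `DNAStringSet`) of reference sequences.
#' @param k k-mer length.
#' @param quantile removal quantile in [0, 1) (default 0.95).
#' @return character vector of k-mers to remove.
#' @export
high_frequency_kmers <- function(seqs, k, quantile = 0.95) {
  stopifnot(quantile >= 0, quantile < 1)
  pooled <- Reduce(`+`, lapply(as.character(seqs), kmer_counts, k = k))
  freq <- pooled / sum(pooled)
  thr <- stats::quantile(freq, quantile, names = FALSE)
  names(freq)[freq > thr]
}

profile_vec <- function(p) {
  if (inherits(p, "kmer_profile")) p$frequencies else p
}

#' Pearson distance between two k-mer profiles
#'
#' d = 1 - r over the k-mers retained in both profiles; ranges over [0, 2].
#'
#' @param p,q `kmer_profile` objects or plain frequency vectors.
#' @return numeric distance.
#' @export
pearson_distance <- function(p, q) {
  x <- profile_vec(p); y <- profile_vec(q)
  stopifnot(length(x) == length(y))
  if (inherits(p, "kmer_profile") || inherits(q, "kmer_profile")) {
    drop <- union(if (inherits(p, "kmer_profile")) p$removed_kmers else NULL,
                  if (inherits(q, "kmer_profile")) q$removed_kmers else NULL)
    keep <- !(names(x) %in% drop)
    x <- x[keep]; y <- y[keep]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (isTRUE(all.equal(x, y))) return(0)
    stop("degenerate profile: correlation undefined")
  }
  1 - stats::cor(x, y)
}

xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Jensen-Shannon divergence between two frequency profiles
#'
#' JSD(p, q) = H(m) - (H(p) + H(q)) / 2 with m = (p + q)/2, logarithms base
#' 2 and 0 log 0 := 0; symmetric and bounded in [0, 1], zero iff the
#' retained profiles are identical.
#'
#' @param p,q `kmer_profile` objects or probability vectors.
#' @return numeric divergence in [0, 1].
#' @export
js_divergence <- function(p, q) {
  x <- profile_vec(p); y <- profile_vec(q)
  stopifnot(length(x) == length(y))
  x <- x / sum(x); y <- y / sum(y)
  m <- (x + y) / 2
  jsd <- -sum(xlog2x(m)) + (sum(xlog2x(x)) + sum(xlog2x(y))) / 2
  min(max(jsd, 0), 1)
}

#' Shannon entropy of a frequency profile (bits)
#'
#' @param p `kmer_profile` or probability vector.
#' @return entropy in bits; 0 for a point mass, log2(length) for uniform.
#' @export
profile_entropy <- function(p) {
  x <- profile_vec(p)
  x <- x / sum(x)
  -sum(xlog2x(x))
}

## ---- F84 pairwise distance ---------------------------------------------

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Summarize an aligned sequence pair for F84
#'
#' Drops columns where either sequence has a gap or an ambiguous base, then
#' computes the proportion of transitions P, transversions Q, and empirical
#' base frequencies over the concatenated pair.
#'
#' @param a,b equal-length aligned sequences (character scalars; `-` or `.`
#'   for gaps).
#' @return list with `L` (usable columns), `P`, `Q`, `pi` (named A/C/G/T
#'   frequencies), `ts_tv_ratio` (observed P/Q, Inf when Q = 0).
#' @export
aligned_pair_summary <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop("aligned sequences must have equal length")
  ok <- x %in% names(TRANSITIONS) & y %in% names(TRANSITIONS)
  x <- x[ok]; y <- y[ok]
  L <- length(x)
  if (L == 0L) stop("no usable aligned column")
  diff <- x != y
  ts <- diff & (TRANSITIONS[x] == y)
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  tab <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
  list(L = L, P = P, Q = Q, pi = as.vector(tab) / sum(tab),
       ts_tv_ratio = if (Q > 0) P / Q else Inf)
}

f84_abc <- function(pi) {
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  list(A = piA * piG / piR + piC * piT / piY,
       B = piA * piG + piC * piT,
       C = piR * piY)
}

#' Closed-form F84 distance for an aligned pair
#'
#' With transition proportion P, transversion proportion Q and base
#' frequencies pi estimated from the pair, and
#'   A = piA piG / piR + piC piT / piY,  B = piA piG + piC piT,  C = piR piY,
#' the distance is
#'   d = -2A log(1 - P/(2A) - (A - B) Q / (2AC)) + 2(A - B - C) log(1 - Q/(2C)).
#' Base frequencies are empirical from the concatenated pair.  The expected
#' transition/transversion ratio conventionally reported alongside (default
#' 2.0) does not enter the closed form, which inverts the observed P and Q
#' directly; the observed ratio is returned in the summary.
#'
#' @param a,b equal-length aligned sequences.
#' @param ts_tv_ratio expected ratio recorded with the result (convention of
#'   the classic distance programs; not used by the closed form).
#' @param summary optional precomputed [aligned_pair_summary()].
#' @return list with `distance`, `summary`.
#' @export
f84_distance <- function(a, b, ts_tv_ratio = 2.0, summary = NULL) {
  s <- summary %||% aligned_pair_summary(a, b)
  if (s$P == 0 && s$Q == 0)
    return(list(distance = 0, summary = s))
  cf <- f84_abc(s$pi)
  arg1 <- 1 - s$P / (2 * cf$A) - (cf$A - cf$B) * s$Q / (2 * cf$A * cf$C)
  arg2 <- 1 - s$Q / (2 * cf$C)
  if (arg1 <= 0 || arg2 <= 0)
    stop("F84 distance saturated: divergence too high for the model")
  d <- -2 * cf$A * log(arg1) + 2 * (cf$A - cf$B - cf$C) * log(arg2)
  list(distance = unname(d), summary = s)
}
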