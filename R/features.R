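# Promoter-level and gene-level covariates: promoter extraction, 4-mer
# composition Z-scores, TE overlap, nucleosome occupancy, tissue-specificity
# entropy.

#' Promoter interval of a gene
#'
#' The promoter is the region immediately upstream of the transcription
#' start site on the gene strand, at most `length` bp (default 500), clipped
#' at the chromosome boundary.  Coordinates are 0-based half-open.
#'
#' @param gene one-row gene model (data.frame with chrom/start/end/strand).
#' @param length promoter length in bp.
#' @param chrom_len chromosome length for clipping (Inf to skip the
#'   right-side clip).
#' @return list with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_interval <- function(gene, length = 500L, chrom_len = Inf) {
  stopifnot(nrow(gene) == 1L)
  if (gene$strand == "+") {
    start <- max(0L, gene$start - length)
    end <- gene$start
  } else {
    start <- gene$end
    end <- min(chrom_len, gene$end + length)
  }
  if (end <= start) stop("promoter of gene ", gene$gene_id,
                         " is empty after clipping")
  list(gene_id = gene$gene_id, chrom = gene$chrom,
       start = as.integer(start), end = as.integer(end),
       strand = gene$strand)
}

#' Promoter intervals for a set of genes
#'
#' Vectorized [promoter_interval()]; genes whose promoter is empty after
#' clipping are dropped with a warning.
#'
#' @param genes gene-model data.frame.
#' @param length promoter length in bp.
#' @param chrom_lens named vector of chromosome lengths (optional).
#' @return data.frame with gene_id, chrom, start, end, strand.
#' @export
promoter_intervals <- function(genes, length = 500L, chrom_lens = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - length), genes$end)
  end <- ifelse(plus, genes$start, genes$end + length)
  if (!is.null(chrom_lens))
    end <- pmin(end, unname(chrom_lens[genes$chrom]))
  keep <- end > start
  if (any(!keep)) warning(sum(!keep), " empty promoter(s) dropped")
  data.frame(gene_id = genes$gene_id[keep], chrom = genes$chrom[keep],
             start = as.integer(start[keep]), end = as.integer(end[keep]),
             strand = genes$strand[keep], stringsAsFactors = FALSE)
}

#' 4-mer composition Z-scores of a promoter class against a reference
#'
#' Pools overlapping 4-mer counts within the class set and within the
#' reference set (the promoters of orthologs unmarked in all species), and
#' computes for every 4-mer a two-proportion Z statistic
#'   Z = (f1 - f0) / sqrt(fbar (1 - fbar) (1/n1 + 1/n0))
#' where f1, f0 are the pooled frequencies, n1, n0 the total 4-mer windows
#' per set and fbar the pooled frequency across both sets.  Positive Z means
#' the 4-mer is enriched in the class relative to the reference.  A 4-mer
#' absent from both sets scores 0 by convention.  `method = "per_promoter"`
#' instead compares the mean per-promoter frequency via a Welch-type Z.
#'
#' @param class_promoters,ref_promoters character vectors (or
#'   `DNAStringSet`) of promoter sequences; both non-empty.
#' @param method `"pooled"` (default) or `"per_promoter"`.
#' @return data.frame with 256 rows: `kmer`, `f_class`, `f_ref`, `z`.
#' @export
fourmer_zscores <- function(class_promoters, ref_promoters,
                            method = c("pooled", "per_promoter")) {
  method <- match.arg(method)
  if (!length(class_promoters) || !length(ref_promoters))
    stop("both promoter sets must be non-empty")
  k <- 4L
  km <- all_kmers(k)
  count_set <- function(seqs)
    Reduce(`+`, lapply(as.character(seqs), kmer_counts, k = k))
  c1 <- count_set(class_promoters)
  c0 <- count_set(ref_promoters)
  n1 <- sum(c1); n0 <- sum(c0)
  f1 <- c1 / n1; f0 <- c0 / n0
  if (method == "pooled") {
    fbar <- (c1 + c0) / (n1 + n0)
    se <- sqrt(fbar * (1 - fbar) * (1 / n1 + 1 / n0))
    z <- ifelse(se > 0, (f1 - f0) / se, 0)
  } else {
    freq_rows <- function(seqs) t(vapply(as.character(seqs), function(s) {
      cnt <- kmer_counts(s, k); cnt / max(1L, sum(cnt))
    }, numeric(length(km))))
    m1 <- freq_rows(class_promoters); m0 <- freq_rows(ref_promoters)
    se <- sqrt(apply(m1, 2, stats::var) / nrow(m1) +
               apply(m0, 2, stats::var) / nrow(m0))
    z <- ifelse(se > 0, (colMeans(m1) - colMeans(m0)) / se, 0)
  }
  data.frame(kmer = km, f_class = as.numeric(f1), f_ref = as.numeric(f0),
             z = as.numeric(z), stringsAsFactors = FALSE)
}

#' Does a promoter harbor a transposable element?
#'
#' A promoter harbors a TE when their overlap exceeds half the TE length
#' (strictly: overlap > 0.5 x TE length).  With several TEs, any passing TE
#' suffices.
#'
#' @param promoter list/one-row data.frame with chrom/start/end.
#' @param tes data.frame of TE intervals (chrom/start/end).
#' @return logical scalar.
#' @export
te_overlap_flag <- function(promoter, tes) {
  if (nrow(tes) == 0L) return(FALSE)
  same <- tes$chrom == promoter$chrom
  if (!any(same)) return(FALSE)
  tes <- tes[same, , drop = FALSE]
  ov <- pmax(0L, pmin(promoter$end, tes$end) - pmax(promoter$start, tes$start))
  any(ov > 0.5 * (tes$end - tes$start))
}

#' Mean nucleosome-occupancy score over a promoter
#'
#' Averages per-base scores of a bedGraph-style coverage track over promoter
#' positions that have data; uncovered positions are excluded from the mean
#' (sparse tracks must not deflate it).
#'
#' @param promoter list/one-row data.frame with chrom/start/end.
#' @param track data.frame with chrom/start/end/score (0-based half-open).
#' @return mean score, or NA when no promoter base is covered.
#' @export
mean_noc <- function(promoter, track) {
  tr <- track[track$chrom == promoter$chrom, , drop = FALSE]
  if (nrow(tr) == 0L) return(NA_real_)
  ov <- pmax(0L, pmin(promoter$end, tr$end) - pmax(promoter$start, tr$start))
  keep <- ov > 0L
  if (!any(keep)) return(NA_real_)
  sum(tr$score[keep] * ov[keep]) / sum(ov[keep])
}

#' Tissue-specificity Shannon entropy of an expression row
#'
#' Expression levels across tissues are normalized to a probability vector
#' and its entropy (bits) is returned: 0 for expression confined to a single
#' tissue, log2(n_tissues) for uniform expression (log2(5) ~ 2.32 with the
#' standard five tissues). Low entropy therefore means high tissue
#' specificity.
#'
#' @param expression numeric vector of non-negative per-tissue levels.
#' @return entropy in bits, or NA for an all-zero row.
#' @export
tissue_entropy <- function(expression) {
  stopifnot(all(expression >= 0, na.rm = TRUE))
  tot <- sum(expression, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- expression / tot
  -sum(xlog2x(p), na.rm = TRUE)
}

#' Tissue entropy for every gene of an expression matrix
#'
#' @param expr data.frame/matrix, genes x tissues (see
#'   [read_expression_matrix()]).
#' @return data.frame with gene_id and entropy (bits).
#' @export
tissue_entropy_table <- function(expr) {
  m <- as.matrix(expr)
  data.frame(gene_id = rownames(m),
             entropy = apply(m, 1L, tissue_entropy),
             stringsAsFactors = FALSE, row.names = NULL)
}
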