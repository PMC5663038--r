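# Contact-map analyses: weak/moderate/strong classification of binned
# intra-chromosomal contacts, co-occurrence of marked genes with
# high-connectivity regions, and distance distributions of strong contacts
# per synteny-block category.

#' Classify contact strength from a score
#'
#' Scores live in [0, 2] (with an optional saturated/"white" state).  The
#' published two-decimal boundaries (weak up to 0.59, moderate 0.60-1.29,
#' strong from 1.30) are reproduced by the half-open intervals
#' [0, 0.60), [0.60, 1.30), [1.30, 2]; scores strictly between the printed
#' boundaries (e.g. 0.595) fall to the lower class.  Saturated cells are
#' strong.
#'
#' @param score numeric vector in [0, 2]; NA allowed where `saturated`.
#' @param saturated logical vector (recycled) flagging saturated cells.
#' @return character vector in `{weak, moderate, strong}`.
#' @export
classify_contact <- function(score, saturated = FALSE) {
  saturated <- rep_len(saturated, length(score))
  if (any(!saturated & (is.na(score) | score < 0 | score > 2)))
    stop("contact score outside [0, 2] and not saturated")
  out <- ifelse(saturated, "strong",
         ifelse(score < 0.60, "weak",
         ifelse(score < 1.30, "moderate", "strong")))
  out
}

#' Flatten a contact matrix to per-contact records
#'
#' One record per unordered bin pair (i <= j) with its score, strength class
#' and genomic distance |i - j| * bin_size.
#'
#' @param cm `contact_matrix` object.
#' @param keep_diagonal keep i == j self-contacts (default TRUE).
#' @return data.frame with bin_i, bin_j (1-based), score, saturated,
#'   strength, distance (bp).
#' @export
contact_records <- function(cm, keep_diagonal = TRUE) {
  n <- nrow(cm$scores)
  idx <- which(upper.tri(cm$scores, diag = keep_diagonal), arr.ind = TRUE)
  score <- cm$scores[idx]
  sat <- cm$saturated[idx]
  data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
             score = score, saturated = sat,
             strength = classify_contact(score, sat),
             distance = (idx[, 2] - idx[, 1]) * cm$bin_size)
}

bin_interval_overlap <- function(bins, bin_size, intervals) {
  # bins: integer vector of 1-based bin indices; intervals on same chrom
  starts <- (bins - 1L) * bin_size
  ends <- bins * bin_size
  vapply(seq_along(bins), function(i)
    any(intervals$start < ends[i] & intervals$end > starts[i]), logical(1))
}

#' Proportion of marked genes overlapping high-connectivity regions
#'
#' For each gene set (all marked genes, plastic, constrained) within each
#' synteny-block category, the proportion of genes overlapping at least
#' `min_overlap` bp of a high-connectivity region, and a Fisher exact test
#' of each class set against the all-marked background of the same
#' category.
#'
#' @param genes data.frame of marked genes with columns gene_id, chrom,
#'   start, end, `class` (plastic/constrained) and optionally
#'   `block_category`; genes without a category fall into `"all_blocks"`.
#' @param regions data.frame of high-connectivity intervals (chrom, start,
#'   end).
#' @param min_overlap minimum intersection in bp to count as overlapping
#'   (default 1).
#' @return data.frame with block_category, gene_set, n_genes, n_overlap,
#'   proportion, fisher_p (NA for the background rows).
#' @export
overlap_proportions <- function(genes, regions, min_overlap = 1L) {
  if (!"block_category" %in% names(genes))
    genes$block_category <- "all_blocks"
  ov <- vapply(seq_len(nrow(genes)), function(i) {
    r <- regions[regions$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    inter <- pmin(genes$end[i], r$end) - pmax(genes$start[i], r$start)
    any(inter >= min_overlap)
  }, logical(1))
  rows <- list()
  for (cat in unique(genes$block_category)) {
    in_cat <- genes$block_category == cat
    bg_n <- sum(in_cat); bg_k <- sum(ov[in_cat])
    rows[[length(rows) + 1L]] <- data.frame(
      block_category = cat, gene_set = "all_marked", n_genes = bg_n,
      n_overlap = bg_k, proportion = if (bg_n) bg_k / bg_n else NA_real_,
      fisher_p = NA_real_, stringsAsFactors = FALSE)
    for (cls in intersect(c("plastic", "constrained"), unique(genes$class))) {
      sel <- in_cat & genes$class == cls
      n <- sum(sel); k <- sum(ov[sel])
      p <- if (n > 0 && bg_n > n) {
        tab <- matrix(c(k, n - k, bg_k - k, bg_n - n - (bg_k - k)), 2L)
        fisher_cooccurrence(tab)$p_value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        block_category = cat, gene_set = cls, n_genes = n, n_overlap = k,
        proportion = if (n) k / n else NA_real_, fisher_p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Distance distribution of strong contacts per synteny-block category
#'
#' For each block category, collects the genomic distances of strong
#' contacts with at least one anchor bin intersecting a block of that
#' category (a contact touching blocks of two categories counts in both),
#' and returns the empirical CDF plus pairwise two-sample
#' Kolmogorov-Smirnov comparisons.
#'
#' @param contacts data.frame from [contact_records()] (one chromosome).
#' @param blocks data.frame with chrom, start, end, category; coordinates
#'   on the contact matrix chromosome.
#' @param bin_size contact bin width in bp.
#' @param chrom chromosome of the contact matrix.
#' @return list with `distances` (named list per category), `ecdf` (named
#'   list of stats::ecdf objects, NULL for empty categories), `ks` (data
#'   frame of pairwise KS statistic and p; NA when a side is empty).
#' @export
strong_contact_distance_ecdf <- function(contacts, blocks,
                                         bin_size = 20000L, chrom = "chr1") {
  strong <- contacts[contacts$strength == "strong", , drop = FALSE]
  cats <- unique(blocks$category)
  dists <- stats::setNames(lapply(cats, function(cat) {
    bl <- blocks[blocks$category == cat & blocks$chrom == chrom, ,
                 drop = FALSE]
    if (!nrow(bl) || !nrow(strong)) return(numeric(0))
    hit_i <- bin_interval_overlap(strong$bin_i, bin_size, bl)
    hit_j <- bin_interval_overlap(strong$bin_j, bin_size, bl)
    strong$distance[hit_i | hit_j]
  }), cats)
  ecdfs <- lapply(dists, function(d) if (length(d)) stats::ecdf(d) else NULL)
  ks <- NULL
  if (length(cats) >= 2L) {
    prs <- utils::combn(cats, 2L)
    ks <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      d1 <- dists[[prs[1, i]]]; d2 <- dists[[prs[2, i]]]
      if (length(d1) && length(d2)) {
        kt <- suppressWarnings(stats::ks.test(d1, d2))
        data.frame(cat_a = prs[1, i], cat_b = prs[2, i],
                   ks_stat = unname(kt$statistic), p_value = kt$p.value,
                   stringsAsFactors = FALSE)
      } else data.frame(cat_a = prs[1, i], cat_b = prs[2, i],
                        ks_stat = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE)
    }))
  }
  list(distances = dists, ecdf = ecdfs, ks = ks)
}
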