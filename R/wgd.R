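# Ohnolog detection via double conserved synteny (DCS): find pairs of
# regions in a duplicated genome that are each syntenic with a single
# region of an unduplicated outgroup genome, then call duplicate pairs
# whose members sit on the two distinct chromosomes of the same DCS block.
# Tandem duplicates (same chromosome, nearby gene positions) are excluded —
# they postdate the whole-genome duplication.

#' Find double-conserved-synteny blocks
#'
#' Slides a window of `window` consecutive outgroup genes along the
#' outgroup gene order; within a window, the mapped genes of the duplicated
#' species are grouped by chromosome and the two best-supported
#' chromosomes are taken.  A window is a DCS candidate when those two
#' chromosomes are distinct and each carries at least `min_support` mapped
#' anchors.  Consecutive candidate windows with the same chromosome pair
#' are merged into one block.
#'
#' @param outgroup_genes data.frame with `gene_id`, `pos` (gene order index
#'   in the outgroup genome), sorted by pos.
#' @param ortholog_map data.frame with `outgroup_gene`, `dup_gene`: each
#'   outgroup gene maps to up to two genes of the duplicated species.
#' @param dup_genes data.frame with `gene_id`, `chrom`, `pos` (gene order
#'   index within its chromosome) for the duplicated species.
#' @param window window length in outgroup genes (default 20).
#' @param min_support minimum anchors per chromosome (default 3).
#' @return list of blocks; each block is a list with `block_id`,
#'   `outgroup_gene_ids`, `chroms` (length 2), `anchors` (named list of dup
#'   gene ids per chromosome).
#' @export
find_dcs_blocks <- function(outgroup_genes, ortholog_map, dup_genes,
                            window = 20L, min_support = 3L) {
  if (nrow(ortholog_map) == 0L || nrow(outgroup_genes) < window)
    return(list())
  og <- outgroup_genes[order(outgroup_genes$pos), , drop = FALSE]
  chrom_of <- stats::setNames(dup_genes$chrom, dup_genes$gene_id)
  n_win <- nrow(og) - window + 1L
  pair_of_window <- character(n_win)
  for (w in seq_len(n_win)) {
    ids <- og$gene_id[w:(w + window - 1L)]
    hits <- ortholog_map[ortholog_map$outgroup_gene %in% ids, , drop = FALSE]
    if (!nrow(hits)) { pair_of_window[w] <- NA_character_; next }
    tab <- sort(table(chrom_of[hits$dup_gene]), decreasing = TRUE)
    if (length(tab) < 2L || tab[2] < min_support) {
      pair_of_window[w] <- NA_character_
    } else {
      pair_of_window[w] <- paste(sort(names(tab)[1:2]), collapse = "|")
    }
  }
  # merge consecutive windows with the same chromosome pair
  blocks <- list()
  w <- 1L
  while (w <= n_win) {
    if (is.na(pair_of_window[w])) { w <- w + 1L; next }
    w2 <- w
    while (w2 < n_win && identical(pair_of_window[w2 + 1L],
                                   pair_of_window[w])) w2 <- w2 + 1L
    ids <- og$gene_id[w:(w2 + window - 1L)]
    chroms <- strsplit(pair_of_window[w], "|", fixed = TRUE)[[1]]
    hits <- ortholog_map[ortholog_map$outgroup_gene %in% ids, , drop = FALSE]
    anchors <- lapply(chroms, function(ch)
      hits$dup_gene[chrom_of[hits$dup_gene] == ch])
    names(anchors) <- chroms
    blocks[[length(blocks) + 1L]] <- list(
      block_id = sprintf("dcs%03d", length(blocks) + 1L),
      outgroup_gene_ids = ids, chroms = chroms, anchors = anchors)
    w <- w2 + 1L
  }
  blocks
}

#' Call ohnolog pairs from DCS blocks
#'
#' One pair per outgroup anchor that maps to genes on both chromosomes of a
#' DCS block.  Pairs whose members lie on the same chromosome within
#' `tandem_max_gap` gene positions would be tandem duplicates and are
#' excluded (redundant with the distinct-chromosome requirement, retained
#' as a safety net).
#'
#' @param blocks output of [find_dcs_blocks()].
#' @param ortholog_map,dup_genes as in [find_dcs_blocks()].
#' @param tandem_max_gap maximum same-chromosome gene-position gap that
#'   defines a tandem duplicate (default 5).
#' @return data.frame with gene_a, gene_b, chrom_a, chrom_b, dcs_block_id
#'   (deduplicated; gene_a < gene_b lexicographically).
#' @export
call_ohnolog_pairs <- function(blocks, ortholog_map, dup_genes,
                               tandem_max_gap = 5L) {
  chrom_of <- stats::setNames(dup_genes$chrom, dup_genes$gene_id)
  pos_of <- stats::setNames(dup_genes$pos, dup_genes$gene_id)
  out <- list()
  for (bl in blocks) {
    for (g in bl$outgroup_gene_ids) {
      dups <- ortholog_map$dup_gene[ortholog_map$outgroup_gene == g]
      if (length(dups) < 2L) next
      in_a <- dups[dups %in% bl$anchors[[1]]]
      in_b <- dups[dups %in% bl$anchors[[2]]]
      if (!length(in_a) || !length(in_b)) next
      ga <- in_a[1]; gb <- in_b[1]
      same_chrom <- chrom_of[ga] == chrom_of[gb]
      if (same_chrom &&
          abs(pos_of[ga] - pos_of[gb]) <= tandem_max_gap) next
      if (same_chrom) next  # distinct-chromosome requirement
      pr <- sort(c(ga, gb))
      out[[length(out) + 1L]] <- data.frame(
        gene_a = pr[1], gene_b = pr[2],
        chrom_a = unname(chrom_of[pr[1]]), chrom_b = unname(chrom_of[pr[2]]),
        dcs_block_id = bl$block_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      dcs_block_id = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$gene_a, res$gene_b)), , drop = FALSE]
}
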