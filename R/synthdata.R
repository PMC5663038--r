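# Seeded generators for every input the pipeline consumes, so that all
# stages are testable without external downloads.
#
# The cross-species marking generator uses a latent ancestral-target
# mechanism: each ortholog is an ancestral PRC2 target with probability
# theta; targets are marked in each species with probability rho (high rho
# yields the correlated, constrained-like patterns), non-targets are marked
# independently in each species at a low switch rate (the plastic-like,
# lineage-specific regime). This latent mechanism is a deliberately simple
# stand-in for unmodeled evolutionary history; it spans the observed
# pattern space, which is all the downstream statistics need.

#' Synthetic-data configuration
#'
#' All generator parameters with their defaults, plus the mandatory seed.
#' Every generated dataset records this configuration (see
#' [write_synthetic_dataset()]), enabling parameter-recovery tests.
#'
#' @param seed integer seed (mandatory; every generator derives its RNG
#'   state from it).
#' @param n_orthologs number of single-copy orthologs (default 13515, the
#'   size of the real three-species single-descendant set).
#' @param theta ancestral PRC2-target probability (default 0.15).
#' @param rho per-species realization probability of the ancestral target
#'   state (default 0.8).
#' @param switch_rate independent per-species marking rate outside the
#'   ancestral-target regime (default 0.05).
#' @param k4_theta,k4_rho,k4_switch same mechanism for the active mark,
#'   which is far more concordant (defaults 0.85 / 0.97 / 0.02).
#' @param outgroup_rate_constrained,outgroup_rate_other probability that an
#'   ortholog also carries the repressive mark in the distant outgroup
#'   clade, for three-species-marked vs other marked orthologs (defaults
#'   0.26 / 0.13, the scale of the published cross-clade fractions).
#' @param promoter_length promoter length in bp (default 500).
#' @param at_boost additive AT-composition boost delta for
#'   constrained-class promoters (default 0.05).
#' @param base_composition baseline A/C/G/T probabilities (default
#'   c(.3, .2, .2, .3), AT-rich as plant intergenic sequence is).
#' @param n_tissues number of tissues (default 5).
#' @param alpha_constrained,alpha_plastic Dirichlet concentrations for
#'   tissue expression profiles; lower concentration = more tissue-specific
#'   (defaults 0.3 / 2).
#' @param block_size mean synteny-block length in genes (default 30).
#' @param enrich_factor class-enrichment factor injected into designated
#'   blocks (default 3).
#' @param frac_enriched fraction of blocks designated as enriched per class
#'   (default 0.1).
#' @param bin_size contact-matrix bin width in bp (default 20000).
#' @param contact_base,contact_decay,contact_noise_sd contact score model:
#'   score(i,j) = clip(base * |i-j|^-decay + boost + noise, 0, 2)
#'   (defaults 1.5 / 1 / 0.05).
#' @param contact_boost additive boost for long-range contacts anchored in
#'   designated blocks (default 1.4: lifts them from the decay floor into
#'   the strong class, the phenomenon the boost emulates).
#' @param long_range_frac contacts at distance >= this fraction of the
#'   chromosome count as long-range (default 0.6, the scaled-down analog of
#'   chromosome-arm-scale distances).
#' @param n_outgroup_genes toy outgroup genome size for the WGD generator
#'   (default 200).
#' @param anchor_loss_rate per-copy duplicate loss rate lambda (default 0.1).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_orthologs = 13515L,
                             theta = 0.15, rho = 0.8, switch_rate = 0.05,
                             k4_theta = 0.85, k4_rho = 0.97, k4_switch = 0.02,
                             outgroup_rate_constrained = 0.26,
                             outgroup_rate_other = 0.13,
                             promoter_length = 500L,
                             at_boost = 0.05,
                             base_composition = c(A = 0.3, C = 0.2,
                                                  G = 0.2, T = 0.3),
                             n_tissues = 5L,
                             alpha_constrained = 0.3, alpha_plastic = 2,
                             block_size = 30L, enrich_factor = 3,
                             frac_enriched = 0.1,
                             bin_size = 20000L,
                             contact_base = 1.5, contact_decay = 1,
                             contact_noise_sd = 0.05, contact_boost = 1.4,
                             long_range_frac = 0.6,
                             n_outgroup_genes = 200L,
                             anchor_loss_rate = 0.1) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  probs <- c(theta, rho, switch_rate, k4_theta, k4_rho, k4_switch,
             outgroup_rate_constrained, outgroup_rate_other, at_boost,
             frac_enriched, anchor_loss_rate, long_range_frac)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(base_composition) - 1) < 1e-9)
  structure(cfg, class = "synthetic_config")
}

with_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((seed + offset) %% .Machine$integer.max)
  force(expr)
}

#' Generate a three-species ortholog marking table
#'
#' @param config `synthetic_config`.
#' @param config_species species configuration (names used for columns).
#' @return list with `records` (a valid marking table) and `true_class`
#'   (the latent regime per ortholog: `"target"` or `"independent"`).
#' @export
generate_ortholog_table <- function(config,
                                    config_species = species_config()) {
  sp <- config_species$species
  n <- config$n_orthologs
  with_seed(config$seed, 101L, {
    target <- stats::runif(n) < config$theta
    k27 <- sapply(seq_along(sp), function(j)
      as.integer(ifelse(target, stats::runif(n) < config$rho,
                        stats::runif(n) < config$switch_rate)))
    t4 <- stats::runif(n) < config$k4_theta
    k4 <- sapply(seq_along(sp), function(j)
      as.integer(ifelse(t4, stats::runif(n) < config$k4_rho,
                        stats::runif(n) < config$k4_switch)))
    n_marked <- rowSums(k27)
    og_rate <- ifelse(n_marked == 3, config$outgroup_rate_constrained,
                      config$outgroup_rate_other)
    outgroup <- ifelse(n_marked == 0, NA_integer_,
                       as.integer(stats::runif(n) < og_rate))
    rec <- data.frame(protogene_id = sprintf("P%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (j in seq_along(sp)) rec[[paste0("gene_", sp[j])]] <-
      sprintf("%s_g%05d", sp[j], seq_len(n))
    for (j in seq_along(sp)) rec[[paste0("H3K27me3_", sp[j])]] <- k27[, j]
    for (j in seq_along(sp)) rec[[paste0("H3K4me3_", sp[j])]] <- k4[, j]
    rec$outgroup_H3K27me3 <- outgroup
    rec$dup_class <- "single_copy"
    list(records = validate_marking_table(rec, config_species),
         true_class = ifelse(target, "target", "independent"))
  })
}

#' Deterministic fixture reproducing the published pattern counts
#'
#' Builds the 13,515-ortholog single-copy marking table whose pattern
#' tabulation matches the published cross-species concordance table
#' cell-for-cell for both marks, including the outgroup-clade column of the
#' repressive mark.  Patterns are assigned deterministically in blocks of
#' rows (no sampling), so tabulation is exact by construction.
#'
#' @param config_species species configuration.
#' @return a valid marking table with 13,515 rows.
#' @export
table1_marking_table <- function(config_species = species_config()) {
  sp <- config_species$species
  lev <- pattern_levels(config_species)
  k27_counts <- c(1464L, 512L, 97L, 197L, 775L, 327L, 301L, 9842L)
  k27_outgrp <- c(384L, 68L, 10L, 31L, 121L, 44L, 46L, NA)
  k4_counts <- c(10010L, 505L, 280L, 188L, 201L, 291L, 289L, 1751L)
  n <- sum(k27_counts)
  flags_for <- function(counts) {
    m <- matrix(0L, n, 3L, dimnames = list(NULL, sp))
    at <- 1L
    for (i in seq_along(lev)) {
      if (counts[i] == 0L) next
      rows <- at:(at + counts[i] - 1L)
      if (lev[i] != "none") {
        members <- strsplit(lev[i], "+", fixed = TRUE)[[1]]
        m[rows, members] <- 1L
      }
      at <- at + counts[i]
    }
    m
  }
  k27 <- flags_for(k27_counts)
  k4 <- flags_for(k4_counts)
  outgroup <- rep(NA_integer_, n)
  at <- 1L
  for (i in seq_along(lev)) {
    if (k27_counts[i] == 0L) next
    rows <- at:(at + k27_counts[i] - 1L)
    if (!is.na(k27_outgrp[i])) {
      outgroup[rows] <- 0L
      outgroup[rows[seq_len(k27_outgrp[i])]] <- 1L
    }
    at <- at + k27_counts[i]
  }
  rec <- data.frame(protogene_id = sprintf("P%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (s in sp) rec[[paste0("gene_", s)]] <- sprintf("%s_g%05d", s, seq_len(n))
  for (j in seq_along(sp)) rec[[paste0("H3K27me3_", sp[j])]] <- k27[, j]
  for (j in seq_along(sp)) rec[[paste0("H3K4me3_", sp[j])]] <- k4[, j]
  rec$outgroup_H3K27me3 <- outgroup
  rec$dup_class <- "single_copy"
  validate_marking_table(rec, config_species)
}

#' Generate promoter sequences with class-specific composition
#'
#' Multinomial nucleotide sampling; promoters of constrained-class genes
#' get their A and T probabilities boosted by `at_boost`/2 each (C and G
#' reduced accordingly), emulating the published AT-richness contrast.
#'
#' @param config `synthetic_config`.
#' @param class_labels character vector of class labels per promoter
#'   (`"constrained"` triggers the boost).
#' @return named character vector of sequences (names = promoter ids).
#' @export
generate_promoters <- function(config, class_labels) {
  n <- length(class_labels)
  base <- config$base_composition
  boosted <- base + c(config$at_boost / 2, -config$at_boost / 2,
                      -config$at_boost / 2, config$at_boost / 2)
  stopifnot(all(boosted >= 0))
  with_seed(config$seed, 202L, {
    seqs <- vapply(seq_len(n), function(i) {
      p <- if (class_labels[i] == "constrained") boosted else base
      paste(sample(names(base), config$promoter_length, replace = TRUE,
                   prob = p), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("prom%05d", seq_len(n))
    seqs
  })
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g[sample.int(k, 1L)] <- 1
  g / sum(g)
}

#' Generate a tissue expression matrix with class-dependent specificity
#'
#' Each gene's tissue profile is Dirichlet with a class-dependent
#' concentration (constrained-class genes get the lower concentration,
#' hence lower entropy / higher tissue specificity), scaled by a log-normal
#' total expression level.
#'
#' @param config `synthetic_config`.
#' @param class_labels class label per gene.
#' @return matrix genes x tissues with gene ids as rownames.
#' @export
generate_expression <- function(config, class_labels) {
  n <- length(class_labels)
  k <- config$n_tissues
  with_seed(config$seed, 303L, {
    m <- t(vapply(seq_len(n), function(i) {
      alpha <- if (class_labels[i] == "constrained")
        config$alpha_constrained else config$alpha_plastic
      total <- stats::rlnorm(1, meanlog = 3, sdlog = 1)
      total * rdirichlet1(k, alpha)
    }, numeric(k)))
    dimnames(m) <- list(sprintf("gene%05d", seq_len(n)),
                        c("root", "shoot", "flower", "pollen", "seed")[seq_len(k)])
    m
  })
}

#' Generate synteny blocks with injected class enrichment
#'
#' Genes are chopped into consecutive blocks of `block_size` genes (the
#' last block takes the remainder); a fraction of blocks is designated
#' enriched for the plastic or constrained class and filled preferentially (by
#' `enrich_factor` times the base rate) with genes of that class.
#'
#' @param config `synthetic_config`.
#' @param gene_classes character vector of class labels, named by gene id
#'   (names optional; defaults to gene00001...).
#' @return list with `blocks` (data.frame block_id, gene_id), `categories`
#'   (data.frame block_id, category in plastic_enriched /
#'   constrained_enriched / not_enriched).
#' @export
generate_blocks <- function(config, gene_classes) {
  n <- length(gene_classes)
  ids <- names(gene_classes) %||% sprintf("gene%05d", seq_len(n))
  with_seed(config$seed, 404L, {
    nb <- as.integer(ceiling(n / config$block_size))
    sizes <- rep(config$block_size, nb)
    sizes[nb] <- n - (nb - 1L) * config$block_size
    sizes <- sizes[sizes > 0L]
    nb <- length(sizes)
    cat_pool <- c("plastic_enriched", "constrained_enriched")
    category <- rep("not_enriched", nb)
    n_des <- max(0L, round(config$frac_enriched * nb))
    if (n_des > 0) {
      des <- sample.int(nb, min(2L * n_des, nb))
      category[des] <- rep(cat_pool, length.out = length(des))
    }
    base_rate <- sapply(c("plastic", "constrained"),
                        function(cl) mean(gene_classes == cl))
    pool <- seq_len(n)  # indices not yet assigned
    assign_block <- function(size, cat) {
      take <- integer(0)
      if (cat != "not_enriched") {
        cl <- sub("_enriched", "", cat)
        want <- min(1, config$enrich_factor * base_rate[[cl]])
        cls_pool <- pool[gene_classes[pool] == cl]
        n_cls <- stats::rbinom(1L, size, want)
        n_cls <- min(n_cls, length(cls_pool))
        if (n_cls > 0)
          take <- cls_pool[sample.int(length(cls_pool), n_cls)]
      }
      rest_pool <- setdiff(pool, take)
      extra <- rest_pool[sample.int(length(rest_pool), size - length(take))]
      c(take, extra)
    }
    block_rows <- vector("list", nb)
    for (b in seq_len(nb)) {
      members <- assign_block(sizes[b], category[b])
      pool <- setdiff(pool, members)
      block_rows[[b]] <- data.frame(block_id = sprintf("blk%04d", b),
                                    gene_id = ids[members],
                                    stringsAsFactors = FALSE)
    }
    list(blocks = do.call(rbind, block_rows),
         categories = data.frame(block_id = sprintf("blk%04d", seq_len(nb)),
                                 category = category,
                                 stringsAsFactors = FALSE))
  })
}

#' Generate a distance-decaying symmetric contact matrix
#'
#' score(i, j) = clip(base * |i-j|^-decay + boost * [long-range and anchored
#' in a designated bin] + Gaussian noise, 0, 2), symmetrized; the diagonal
#' takes the clip ceiling.  `designated_bins` receive the long-range boost,
#' emulating blocks whose genes engage chromosome-arm-scale contacts.
#'
#' @param config `synthetic_config`.
#' @param n_bins number of bins.
#' @param designated_bins integer vector of boosted bin indices.
#' @return `contact_matrix` object.
#' @export
generate_contacts <- function(config, n_bins, designated_bins = integer(0)) {
  with_seed(config$seed, 505L, {
    i <- matrix(seq_len(n_bins), n_bins, n_bins)
    d <- abs(i - t(i))
    base <- config$contact_base * ifelse(d == 0, 2, d^(-config$contact_decay))
    long <- d >= config$long_range_frac * n_bins
    anch <- matrix(FALSE, n_bins, n_bins)
    if (length(designated_bins)) {
      anch[designated_bins, ] <- TRUE
      anch[, designated_bins] <- TRUE
    }
    noise <- matrix(stats::rnorm(n_bins^2, sd = config$contact_noise_sd),
                    n_bins)
    noise <- (noise + t(noise)) / 2
    sc <- pmin(pmax(base + config$contact_boost * (long & anch) + noise, 0), 2)
    contact_matrix(sc, bin_size = config$bin_size)
  })
}

#' Generate a toy whole-genome-duplication fixture
#'
#' An outgroup genome of `n_outgroup_genes` ordered genes is duplicated
#' onto two chromosome pairs of a toy descendant genome (two consecutive
#' segments map to chromosome pairs d1/d2 and d3/d4); each duplicate copy
#' is then lost independently with probability `anchor_loss_rate`.
#'
#' @param config `synthetic_config`.
#' @return list with `outgroup_genes`, `ortholog_map`, `dup_genes` (inputs
#'   of [find_dcs_blocks()]) and `true_pairs` (data.frame gene_a, gene_b of
#'   duplicate pairs with both copies retained).
#' @export
generate_ohnologs <- function(config) {
  n <- config$n_outgroup_genes
  with_seed(config$seed, 606L, {
    og <- data.frame(gene_id = sprintf("og%04d", seq_len(n)), pos = seq_len(n),
                     stringsAsFactors = FALSE)
    seg <- ifelse(seq_len(n) <= n / 2, 1L, 2L)
    chrom_a <- c("d1", "d3")[seg]
    chrom_b <- c("d2", "d4")[seg]
    keep_a <- stats::runif(n) >= config$anchor_loss_rate
    keep_b <- stats::runif(n) >= config$anchor_loss_rate
    dup <- rbind(
      data.frame(gene_id = sprintf("a%04d", seq_len(n))[keep_a],
                 chrom = chrom_a[keep_a], src = which(keep_a),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = sprintf("b%04d", seq_len(n))[keep_b],
                 chrom = chrom_b[keep_b], src = which(keep_b),
                 stringsAsFactors = FALSE))
    dup <- dup[order(dup$chrom, dup$src), , drop = FALSE]
    dup$pos <- stats::ave(dup$src, dup$chrom, FUN = seq_along)
    omap <- rbind(
      data.frame(outgroup_gene = og$gene_id[keep_a],
                 dup_gene = sprintf("a%04d", which(keep_a)),
                 stringsAsFactors = FALSE),
      data.frame(outgroup_gene = og$gene_id[keep_b],
                 dup_gene = sprintf("b%04d", which(keep_b)),
                 stringsAsFactors = FALSE))
    both <- which(keep_a & keep_b)
    true_pairs <- data.frame(gene_a = sprintf("a%04d", both),
                             gene_b = sprintf("b%04d", both),
                             stringsAsFactors = FALSE)
    list(outgroup_genes = og,
         ortholog_map = omap,
         dup_genes = dup[, c("gene_id", "chrom", "pos")],
         true_pairs = true_pairs)
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every standard-format file the pipeline consumes (marking table,
#' promoter FASTA, expression TSV, synteny-block TSV, contact-matrix TSV)
#' plus a `manifest.json` sidecar recording the full configuration, so any
#' generated dataset documents its own ground truth.
#'
#' @param config `synthetic_config`.
#' @param dir output directory (created if needed).
#' @param n_bins contact-matrix size (default 50 bins).
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_dataset <- function(config, dir, n_bins = 50L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_ortholog_table(config)
  paths <- list(marking = file.path(dir, "marking.tsv"))
  write_marking_table(gen$records, paths$marking)
  cls <- mark_class(gen$records)
  names(cls) <- gen$records$protogene_id
  prom <- generate_promoters(config, cls)
  paths$promoters <- file.path(dir, "promoters.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(prom), paths$promoters)
  expr <- generate_expression(config, cls)
  paths$expression <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                stringsAsFactors = FALSE),
                     paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  names(cls) <- rownames(expr)  # block generator keys on synthetic gene ids
  blk <- generate_blocks(config, cls)
  paths$blocks <- file.path(dir, "blocks.tsv")
  utils::write.table(merge(blk$blocks, blk$categories, by = "block_id"),
                     paths$blocks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cm <- generate_contacts(config, n_bins,
                          designated_bins = seq_len(max(1L, n_bins %/% 10L)))
  paths$contacts <- file.path(dir, "contacts.tsv")
  write_contact_matrix(cm, paths$contacts)
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(config), paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
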