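# Cross-species marking-pattern classification and concordance statistics.
#
# For every single-copy ortholog the per-species 0/1 flags of a mark define a
# pattern (which subset of the three species carries the mark). Patterns with
# the mark in >= 2 species are "concordant". For H3K27me3 the patterns are
# further collapsed into two evolutionary modes:
#   constrained — marked in the outermost species AND in at least one of the
#                 sister pair (parsimony: invariant since the common ancestor)
#   plastic     — marked somewhere, but not constrained (sister pair only, or
#                 exclusively the outermost species)
# For H3K4me3 the collapse is concordant (>= 2 species) vs lineage_specific.

pattern_levels <- function(config = species_config()) {
  sp <- config$species
  subsets <- list(sp, sp[c(1, 2)], sp[c(2, 3)], sp[c(1, 3)],
                  sp[1], sp[2], sp[3], character(0))
  vapply(subsets, function(s) if (length(s)) paste(s, collapse = "+") else "none",
         character(1))
}

mark_matrix <- function(records, mark, config = species_config()) {
  m <- sapply(config$species, function(s) records[[paste0(mark, "_", s)]])
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(records),
                                   dimnames = list(NULL, config$species))
  m
}

#' Classify the cross-species marking pattern of single-copy orthologs
#'
#' @param records marking table restricted to single-copy orthologs (gene
#'   present, hence a 0/1 flag, in all three species).
#' @param mark `"H3K27me3"` or `"H3K4me3"`.
#' @param config species configuration.
#' @return data.frame with columns `protogene_id`, `pattern` (factor over the
#'   8 possible species subsets, `"none"` for unmarked), `n_marked`,
#'   `concordant` (marked in at least two species).
#' @export
classify_pattern <- function(records, mark = "H3K27me3",
                             config = species_config()) {
  mark <- match.arg(mark, MARKS)
  m <- mark_matrix(records, mark, config)
  if (anyNA(m))
    stop("NA marking flag: only single-copy records are admissible")
  keys <- apply(m == 1L, 1L, function(row) {
    s <- config$species[row]
    if (length(s)) paste(s, collapse = "+") else "none"
  })
  n <- rowSums(m)
  data.frame(protogene_id = records$protogene_id,
             pattern = factor(keys, levels = pattern_levels(config)),
             n_marked = as.integer(n),
             concordant = n >= 2L,
             stringsAsFactors = FALSE)
}

#' Collapse H3K27me3 patterns into plastic / constrained / unmarked
#'
#' Constrained: the outermost species and at least one sister-pair species
#' carry the mark. Plastic: marked in at least one species without meeting
#' the constrained rule. Unmarked: no species carries the mark.
#'
#' @param patterns output of [classify_pattern()] for H3K27me3, or a
#'   character vector of pattern keys.
#' @param config species configuration.
#' @return character vector in `{plastic, constrained, unmarked}`.
#' @export
classify_h3k27 <- function(patterns, config = species_config()) {
  keys <- if (is.data.frame(patterns)) as.character(patterns$pattern) else
    as.character(patterns)
  vapply(keys, function(k) {
    if (k == "none") return("unmarked")
    s <- strsplit(k, "+", fixed = TRUE)[[1]]
    if (config$outermost %in% s && any(config$sister_pair %in% s))
      "constrained" else "plastic"
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse H3K4me3 patterns into lineage_specific / concordant / unmarked
#'
#' @inheritParams classify_h3k27
#' @return character vector in `{lineage_specific, concordant, unmarked}`.
#' @export
classify_h3k4 <- function(patterns, config = species_config()) {
  keys <- if (is.data.frame(patterns)) as.character(patterns$pattern) else
    as.character(patterns)
  n <- ifelse(keys == "none", 0L,
              lengths(strsplit(keys, "+", fixed = TRUE)))
  ifelse(n == 0L, "unmarked", ifelse(n >= 2L, "concordant", "lineage_specific"))
}

#' Assign the marking-mode class for a mark
#'
#' Dispatches to [classify_h3k27()] (plastic/constrained) or
#' [classify_h3k4()] (lineage_specific/concordant).
#'
#' @param records single-copy marking table.
#' @param mark mark name.
#' @param config species configuration.
#' @return character vector of class labels, one per record.
#' @export
mark_class <- function(records, mark = "H3K27me3", config = species_config()) {
  pat <- classify_pattern(records, mark, config)
  if (mark == "H3K27me3") classify_h3k27(pat, config) else
    classify_h3k4(pat, config)
}

#' Tabulate marking patterns across the single-copy ortholog set
#'
#' @param records single-copy marking table.
#' @param mark mark name.
#' @param config species configuration.
#' @return object of class `pattern_table`: data.frame with one row per
#'   pattern and columns `pattern`, `count`, `outgroup_count` (records in the
#'   pattern whose ortholog also carries the mark in the distant outgroup
#'   species, where that flag is available).
#' @export
tabulate_patterns <- function(records, mark = "H3K27me3",
                              config = species_config()) {
  lev <- pattern_levels(config)
  if (nrow(records) == 0L) {
    tab <- data.frame(pattern = lev, count = 0L, outgroup_count = 0L,
                      stringsAsFactors = FALSE)
  } else {
    pat <- classify_pattern(records, mark, config)
    cnt <- table(pat$pattern)
    og <- records$outgroup_H3K27me3
    if (is.null(og)) og <- rep(NA_integer_, nrow(records))
    ogc <- tapply(og == 1L, pat$pattern, sum, na.rm = TRUE)
    tab <- data.frame(pattern = lev,
                      count = as.integer(cnt[lev]),
                      outgroup_count = as.integer(ifelse(is.na(ogc[lev]), 0L,
                                                         ogc[lev])),
                      stringsAsFactors = FALSE)
  }
  structure(tab, class = c("pattern_table", "data.frame"),
            mark = mark, config = config)
}

pt_config <- function(table) attr(table, "config") %||% species_config()
`%||%` <- function(a, b) if (is.null(a)) b else a

pattern_sizes <- function(table) {
  lengths(strsplit(as.character(table$pattern), "+", fixed = TRUE)) *
    (table$pattern != "none")
}

#' Concordance summary fractions for a pattern table
#'
#' @param table a `pattern_table`.
#' @return list with `total`, `n_marked_any`, `frac_marked_any` (orthologs
#'   marked in >= 1 species), `frac_concordant` (among marked, >= 2 species),
#'   `frac_single`, `frac_triple` (among marked), and `frac_sister_pair`
#'   (among two-species patterns, share in the sister pair). Empty
#'   denominators yield NA.
#' @export
concordance_summary <- function(table) {
  cfg <- pt_config(table)
  sizes <- pattern_sizes(table)
  total <- sum(table$count)
  marked <- sum(table$count[sizes > 0])
  conc <- sum(table$count[sizes >= 2])
  single <- sum(table$count[sizes == 1])
  triple <- sum(table$count[sizes == 3])
  two <- sum(table$count[sizes == 2])
  sister_key <- paste(cfg$sister_pair, collapse = "+")
  sister <- sum(table$count[as.character(table$pattern) == sister_key])
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(total = total,
       n_marked_any = marked,
       frac_marked_any = frac(marked, total),
       frac_concordant = frac(conc, marked),
       frac_single = frac(single, marked),
       frac_triple = frac(triple, marked),
       frac_sister_pair = frac(sister, two))
}

#' Class sizes implied by a pattern table
#'
#' @param table a `pattern_table` (H3K27me3 semantics: plastic/constrained;
#'   for H3K4me3 use `mark = "H3K4me3"` to get lineage_specific/concordant).
#' @param mark mark whose collapse rule to apply (defaults to the table's).
#' @return named integer vector of counts per class label.
#' @export
class_counts <- function(table, mark = attr(table, "mark")) {
  cfg <- pt_config(table)
  lab <- if (identical(mark, "H3K4me3"))
    classify_h3k4(as.character(table$pattern), cfg) else
    classify_h3k27(as.character(table$pattern), cfg)
  tapply(table$count, lab, sum)
}

#' Independence null for marking-pattern abundances
#'
#' With `base = "marked"` (default), per-species marking probabilities are
#' estimated among the orthologs marked in at least one species; pattern
#' probabilities are then computed under independence across species and
#' renormalized by 1 - P(no species marked), i.e. conditioned on being
#' marked somewhere, so they are comparable to the observed fractions among
#' marked orthologs (this is the convention behind the published
#' expected-by-chance percentages).  With `base = "all"`, marginals are
#' unconditional (per-species marked count over all orthologs) and the
#' expected fractions cover all 8 patterns without conditioning; this is
#' the variant that truly independent marking reproduces exactly, and the
#' one the generator self-consistency checks use.
#'
#' @param table a `pattern_table` with >= 1 marked ortholog.
#' @param base `"marked"` or `"all"` (see Details).
#' @return list with `base`, `marginals` (named per-species probabilities),
#'   `expected` (named pattern probabilities summing to 1 over the 7
#'   non-empty patterns for `"marked"`, over all 8 for `"all"`), and
#'   category aggregates `expected_single`, `expected_double`,
#'   `expected_triple` (for `"marked"`: fractions among marked; for
#'   `"all"`: unconditional fractions).
#' @export
expected_pattern_fractions <- function(table, base = c("marked", "all")) {
  base <- match.arg(base)
  cfg <- pt_config(table)
  sp <- cfg$species
  sizes <- pattern_sizes(table)
  marked <- sum(table$count[sizes > 0])
  if (marked == 0L) stop("no marked ortholog: null model undefined")
  keys <- as.character(table$pattern)
  denom <- if (base == "marked") marked else sum(table$count)
  marg <- vapply(sp, function(s) {
    inpat <- vapply(keys, function(k)
      s %in% strsplit(k, "+", fixed = TRUE)[[1]], logical(1))
    sum(table$count[inpat]) / denom
  }, numeric(1))
  use <- if (base == "marked") keys[sizes > 0] else keys
  probs <- vapply(use, function(k) {
    s <- if (k == "none") character(0) else
      strsplit(k, "+", fixed = TRUE)[[1]]
    prod(ifelse(sp %in% s, marg, 1 - marg))
  }, numeric(1))
  expected <- if (base == "marked") probs / (1 - prod(1 - marg)) else probs
  nsz <- ifelse(use == "none", 0L,
                lengths(strsplit(use, "+", fixed = TRUE)))
  list(base = base,
       marginals = marg,
       expected = expected,
       expected_single = sum(expected[nsz == 1]),
       expected_double = sum(expected[nsz == 2]),
       expected_triple = sum(expected[nsz == 3]))
}

#' Fraction of a pattern category also marked in the distant outgroup clade
#'
#' For Table-style data the outgroup flag records whether the ortholog also
#' carries H3K27me3 in maize and rice; this reports, within a pattern
#' category, the fraction of orthologs with that flag set.
#'
#' @param table a `pattern_table` carrying `outgroup_count`.
#' @param category `"triple"` (all three species; the reading consistent
#'   with the published arithmetic), `"concordant"` (>= 2 species),
#'   `"plastic"`, `"constrained"`, `"discordant"` (marked, not concordant),
#'   or a specific pattern key such as `"Ath+Aly"`.
#' @return fraction in [0, 1], or NA for an empty category.
#' @export
cross_clade_fraction <- function(table, category = "triple") {
  cfg <- pt_config(table)
  sizes <- pattern_sizes(table)
  keys <- as.character(table$pattern)
  sel <- switch(category,
    triple = sizes == 3,
    concordant = sizes >= 2,
    discordant = sizes == 1,
    plastic = classify_h3k27(keys, cfg) == "plastic",
    constrained = classify_h3k27(keys, cfg) == "constrained",
    keys == category)
  n <- sum(table$count[sel])
  if (n == 0L) return(NA_real_)
  sum(table$outgroup_count[sel]) / n
}

#' Per-species marking frequency
#'
#' Fraction of records carrying the mark in a species; records whose gene is
#' absent in that species (NA flag) are excluded from the denominator.
#'
#' @param records marking table (any duplication class).
#' @param species species tag.
#' @param mark mark name.
#' @return fraction, or NA when no record has the gene in that species.
#' @export
marking_frequency <- function(records, species, mark = "H3K27me3") {
  v <- records[[paste0(mark, "_", species)]]
  if (is.null(v)) stop("unknown species: ", species)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v == 1L)
}

#' Fraction of marked records whose marking is restricted to duplicate-bearing species
#'
#' For recently duplicated orthologs, tests whether the mark is confined to
#' the species that contain the gene duplicates: among records marked in at
#' least one species, the fraction whose full set of marked species is a
#' subset of its duplicate-containing species.
#'
#' @param records marking table.
#' @param dup_species list (one element per record) of character vectors of
#'   duplicate-containing species.
#' @param mark mark name.
#' @param config species configuration.
#' @return fraction, or NA when no record is marked.
#' @export
species_restriction_fraction <- function(records, dup_species,
                                         mark = "H3K27me3",
                                         config = species_config()) {
  stopifnot(length(dup_species) == nrow(records))
  m <- mark_matrix(records, mark, config)
  marked_sets <- lapply(seq_len(nrow(records)), function(i)
    config$species[!is.na(m[i, ]) & m[i, ] == 1L])
  has_mark <- lengths(marked_sets) > 0L
  if (!any(has_mark)) return(NA_real_)
  restricted <- mapply(function(ms, ds) all(ms %in% ds),
                       marked_sets[has_mark], dup_species[has_mark])
  mean(restricted)
}
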