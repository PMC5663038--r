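# Data model and readers/writers for the external formats the pipeline
# consumes. All internal coordinates are 0-based half-open; GFF3 (1-based
# closed) is converted on read, BED/bedGraph are native.

#' Default species configuration
#'
#' The comparative framework involves three species: a pair of closely
#' related sister taxa and a more distant third species.  The marking-mode
#' classifier treats the sister pair symmetrically and the outermost species
#' asymmetrically, so the roles must be declared once and passed around.
#'
#' @param species character vector of exactly three species tags.  The first
#'   two are the sister pair, the third is the outermost species.
#' @return a list with elements `species`, `sister_pair`, `outermost`.
#' @examples
#' species_config()
#' species_config(c("spA", "spB", "spC"))
#' @export
species_config <- function(species = c("Ath", "Aly", "Aal")) {
  stopifnot(is.character(species), length(species) == 3L,
            !anyDuplicated(species))
  list(species = species,
       sister_pair = species[1:2],
       outermost = species[3])
}

#' Marks recognised by the pipeline
#' @export
MARKS <- c("H3K27me3", "H3K4me3")

new_gene_model <- function(gene_id, chrom, start, end, strand, species) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   species = as.character(species),
                   stringsAsFactors = FALSE)
  validate_gene_models(df)
}

validate_gene_models <- function(df) {
  if (any(df$start < 0L)) stop("gene coordinates must be non-negative")
  if (any(df$start >= df$end)) stop("gene models require start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(paste(df$species, df$gene_id)))
    stop("gene_id must be unique within species")
  df
}

#' Read gene models from a GFF3 file
#'
#' Extracts features of type `gene` and converts their coordinates from the
#' GFF3 1-based closed convention to the internal 0-based half-open one.
#' Records with unknown strand (`.` or `*`) are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @param species species tag stored on every returned record.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   species (one row per gene; 0-based half-open coordinates).
#' @export
read_gff3 <- function(path, species = "unknown", feature_type = "gene") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in '", path,
                                          "': ", conditionMessage(e)))
  gr <- gr[gr$type == feature_type]
  str <- as.character(GenomicRanges::strand(gr))
  bad <- !(str %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown strand skipped")
    gr <- gr[!bad]
    str <- str[!bad]
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids <- ifelse(is.na(ids), paste0("gene", seq_along(gr)), ids)
  new_gene_model(gene_id = ids,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 strand = str,
                 species = species)
}

## ---- ortholog marking tables -------------------------------------------

mark_flag_cols <- function(species, marks = MARKS) {
  as.vector(outer(marks, species, paste, sep = "_"))
}

#' Read a per-ortholog marking table
#'
#' The table is a TSV with one row per protogene (the ancestral gene that
#' anchors orthology across species).  Expected columns: `protogene_id`;
#' `gene_<sp>` holding the descendant gene id in each species (empty when
#' the gene was lost); `<mark>_<sp>` holding 0/1 marking flags for each
#' (mark, species) combination, empty (NA) only where the gene is absent;
#' optionally `outgroup_H3K27me3` (0/1/NA) and `dup_class`.
#'
#' @param path TSV path.
#' @param config species configuration (see [species_config()]).
#' @return data.frame of ortholog records; flag columns are integer 0/1/NA.
#' @export
read_marking_table <- function(path, config = species_config()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_marking_table(df, config)
}

#' Validate an ortholog marking table
#'
#' Enforces the structural contract: unique protogene ids, flags in {0,1,NA},
#' NA flags exactly where the gene is absent.
#'
#' @param df data.frame shaped as described in [read_marking_table()].
#' @param config species configuration.
#' @return the validated data.frame (flag columns coerced to integer).
#' @export
validate_marking_table <- function(df, config = species_config()) {
  sp <- config$species
  need <- c("protogene_id", paste0("gene_", sp), mark_flag_cols(sp))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marking table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$protogene_id))
    stop("duplicate protogene_id in marking table")
  for (s in sp) {
    present <- !is.na(df[[paste0("gene_", s)]])
    for (m in MARKS) {
      col <- paste0(m, "_", s)
      v <- df[[col]]
      if (!all(v %in% c(0L, 1L, NA)))
        stop("flag column ", col, " must be 0/1/NA")
      v <- as.integer(v)
      if (any(!is.na(v) & !present))
        stop("marking flag set for absent gene in column ", col)
      if (any(is.na(v) & present))
        stop("missing marking flag for present gene in column ", col)
      df[[col]] <- v
    }
  }
  if (!"outgroup_H3K27me3" %in% names(df)) df$outgroup_H3K27me3 <- NA_integer_
  df$outgroup_H3K27me3 <- as.integer(df$outgroup_H3K27me3)
  if (!"dup_class" %in% names(df)) df$dup_class <- "single_copy"
  df
}

#' Write a marking table to TSV
#' @param df ortholog marking table.
#' @param path output path.
#' @export
write_marking_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Restrict a marking table to single-copy records
#'
#' Single-copy records have a descendant gene in all three species; only
#' these enter the cross-species concordance tabulation.
#'
#' @param df marking table.
#' @param config species configuration.
#' @export
single_copy_records <- function(df, config = species_config()) {
  present <- sapply(config$species, function(s) !is.na(df[[paste0("gene_", s)]]))
  df[rowSums(present) == 3L, , drop = FALSE]
}

## ---- contact matrices ---------------------------------------------------

#' Read a dense intra-chromosomal contact matrix
#'
#' The matrix is a square dense TSV of contact scores in [0, 2] between
#' fixed-size genomic bins.  Saturated ("white") cells may be encoded with a
#' sentinel string; they are kept as `NA` scores with a logical saturation
#' mask and always classify as strong contacts downstream.  The matrix is
#' symmetrized by taking the elementwise maximum of the two triangles.
#'
#' @param path TSV path (no header, no row names).
#' @param bin_size bin width in bp (default 20000).
#' @param chrom chromosome label.
#' @param sentinel string marking saturated cells (default `"W"`).
#' @return object of class `contact_matrix`: list with `scores` (numeric
#'   matrix, NA at saturated cells), `saturated` (logical matrix),
#'   `bin_size`, `chrom`.
#' @export
read_contact_matrix <- function(path, bin_size = 20000L, chrom = "chr1",
                                sentinel = "W") {
  raw <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "character"))
  if (nrow(raw) != ncol(raw)) stop("contact matrix must be square")
  sat <- raw == sentinel
  scores <- suppressWarnings(matrix(as.numeric(raw), nrow(raw)))
  if (any(is.na(scores) & !sat)) stop("non-numeric, non-sentinel cell")
  bad <- !is.na(scores) & (scores < 0 | scores > 2)
  if (any(bad)) stop("contact score outside [0, 2]: ",
                     scores[bad][1])
  contact_matrix(scores, bin_size = bin_size, chrom = chrom, saturated = sat)
}

#' Construct a contact matrix object
#' @param scores square numeric matrix, NA allowed where `saturated`.
#' @param bin_size bin width in bp.
#' @param chrom chromosome label.
#' @param saturated logical matrix of saturated ("white") cells.
#' @export
contact_matrix <- function(scores, bin_size = 20000L, chrom = "chr1",
                           saturated = NULL) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores), bin_size > 0)
  if (is.null(saturated)) saturated <- is.na(scores) & FALSE
  # symmetrize by max; saturation propagates symmetrically
  scores2 <- pmax(scores, t(scores), na.rm = FALSE)
  na_one <- is.na(scores) != is.na(t(scores))
  scores2[na_one] <- pmax(scores, t(scores), na.rm = TRUE)[na_one]
  saturated <- saturated | t(saturated)
  scores2[saturated] <- NA_real_
  structure(list(scores = scores2, saturated = saturated,
                 bin_size = as.integer(bin_size), chrom = chrom),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %d bp, %d saturated cell(s)\n",
              x$chrom, nrow(x$scores), x$bin_size, sum(x$saturated)))
  invisible(x)
}

#' Write a contact matrix as dense TSV
#' @param cm `contact_matrix` object.
#' @param path output path.
#' @param sentinel string used for saturated cells.
#' @export
write_contact_matrix <- function(cm, path, sentinel = "W") {
  out <- matrix(format(cm$scores, trim = TRUE, digits = 15), nrow(cm$scores))
  out[cm$saturated] <- sentinel
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- other tabular inputs ----------------------------------------------

#' Read a tissue-by-gene expression matrix
#'
#' TSV with a `gene_id` column followed by one column per tissue; values are
#' non-negative expression levels.
#'
#' @param path TSV path.
#' @return data.frame with rownames = gene ids, one column per tissue.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(df))
  rn <- df$gene_id
  df$gene_id <- NULL
  m <- as.data.frame(df)
  rownames(m) <- rn
  if (any(as.matrix(m) < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  m
}

#' Read synteny-block assignments
#'
#' TSV with columns `block_id`, `gene_id` (one row per gene; blocks are runs
#' of genes with conserved order against the ancestral genome, produced by
#' external synteny software and consumed here as given).
#'
#' @param path TSV path.
#' @export
read_synteny_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("block_id", "gene_id") %in% names(df)))
  df
}

#' Read a BED file of genomic intervals
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param path BED path.
#' @return data.frame with columns chrom, start, end (and name if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a bedGraph coverage track
#' @param path bedGraph path.
#' @return data.frame with columns chrom, start, end, score (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score,
             stringsAsFactors = FALSE)
}
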