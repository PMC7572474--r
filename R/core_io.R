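#' Read and write the pipeline's tab-separated tables
#'
#' All tables used by the pipeline are plain TSV files with a mandatory header
#' row and case-sensitive identifiers. `read_tsv_table()` and
#' `write_tsv_table()` round-trip these files bit-exactly (no quoting, no row
#' names, `NA` written as empty fields).
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return `read_tsv_table()` returns a `data.frame`; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("missing column(s) in ", basename(path), ": ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_tsv_table
#' @param df data frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read gene annotations
#'
#' The annotation table maps genes to their rMAG of origin and carries the
#' functional assignments used throughout the pipeline: the KEGG ortholog
#' group (`ko_id`) and the top-level FOAM ontology category (`foam_l1`), both
#' optional per gene. A gene may appear on several rows when it has several
#' FOAM L1 assignments; its (gene, rMAG, KO, length) fields must then agree.
#'
#' @param path TSV with columns gene_id, rmag_id, ko_id, foam_l1, length_bp.
#' @return data.frame with those columns; `ko_id`/`foam_l1` may be `NA`.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_table(path, c("gene_id", "rmag_id", "ko_id", "foam_l1",
                               "length_bp"))
  df$length_bp <- as.integer(df$length_bp)
  if (any(is.na(df$length_bp)) || any(df$length_bp < 1L))
    stop("length_bp must be a positive integer for every gene", call. = FALSE)
  key <- !duplicated(df$gene_id)
  per_gene <- df[key, c("gene_id", "rmag_id", "length_bp")]
  m <- merge(df, per_gene, by = "gene_id", suffixes = c("", ".first"))
  if (any(m$rmag_id != m$rmag_id.first | m$length_bp != m$length_bp.first))
    stop("gene_id rows disagree on rmag_id or length_bp", call. = FALSE)
  df
}

#' Read a depth table
#'
#' One row per (feature, sample); `feature_id` is a gene or contig id.
#'
#' @param path TSV with columns feature_id, sample_id, summed_depth, length_bp.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  df <- read_tsv_table(path, c("feature_id", "sample_id", "summed_depth",
                               "length_bp"))
  df$summed_depth <- as.numeric(df$summed_depth)
  df$length_bp <- as.integer(df$length_bp)
  df
}

#' Read a genome quality table
#'
#' Completeness and contamination are stored as fractions in `[0, 1]`. Tables
#' exported as percentages are accepted with `percent = TRUE`, which divides
#' both columns by 100.
#'
#' @param path TSV with columns mag_id, completeness, contamination, kingdom.
#' @param percent logical; are completeness/contamination given in percent?
#' @return data.frame with fractional completeness/contamination.
#' @export
read_quality_table <- function(path, percent = FALSE) {
  df <- read_tsv_table(path, c("mag_id", "completeness", "contamination"))
  if (!"kingdom" %in% names(df)) df$kingdom <- NA_character_
  df$completeness <- as.numeric(df$completeness)
  df$contamination <- as.numeric(df$contamination)
  if (percent) {
    df$completeness <- df$completeness / 100
    df$contamination <- df$contamination / 100
  }
  rng <- range(c(df$completeness, df$contamination), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("completeness/contamination outside [0, 1]; ",
         "use percent = TRUE for percentage tables", call. = FALSE)
  df
}

#' Compute depth of coverage from summed per-base depth
#'
#' Depth of coverage of a feature in a sample is the summed per-base depth
#' divided by the feature length. Feature/sample combinations absent from the
#' input are reported as depth 0, so downstream ratio rules always see
#' explicit zeros.
#'
#' @param records data.frame with feature_id, sample_id, summed_depth,
#'   length_bp (one row per feature and sample).
#' @return numeric matrix, features x samples, of depth of coverage.
#' @export
compute_depth <- function(records) {
  stopifnot(all(c("feature_id", "sample_id", "summed_depth", "length_bp")
                %in% names(records)))
  if (any(records$length_bp <= 0))
    stop("length_bp must be positive; offending feature(s): ",
         paste(unique(records$feature_id[records$length_bp <= 0]),
               collapse = ", "), call. = FALSE)
  key <- paste(records$feature_id, records$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate depth record for (feature, sample) = (",
         gsub("\r", ", ", dup), ")", call. = FALSE)
  }
  feats <- unique(records$feature_id)
  samps <- unique(records$sample_id)
  M <- matrix(0, length(feats), length(samps),
              dimnames = list(feats, samps))
  M[cbind(match(records$feature_id, feats),
          match(records$sample_id, samps))] <-
    records$summed_depth / records$length_bp
  M
}

#' Aggregate contig depths to rMAG depth of coverage
#'
#' rMAG depth is the length-weighted mean coverage of its member contigs:
#' the total summed per-base depth over all member contigs divided by the
#' total contig length. Contigs without an rMAG assignment are excluded with
#' a warning that reports how many were dropped.
#'
#' @param contig_records data.frame with feature_id, sample_id, summed_depth,
#'   length_bp at the contig level.
#' @param contig_to_rmag named character vector mapping contig id to rMAG id.
#' @return numeric matrix, rMAGs x samples, of depth of coverage.
#' @export
rmag_depth <- function(contig_records, contig_to_rmag) {
  rmag <- contig_to_rmag[contig_records$feature_id]
  unmapped <- is.na(rmag)
  if (any(unmapped)) {
    warning(sum(unmapped), " contig depth record(s) without an rMAG mapping ",
            "were excluded", call. = FALSE)
    contig_records <- contig_records[!unmapped, , drop = FALSE]
    rmag <- rmag[!unmapped]
  }
  if (!nrow(contig_records)) stop("no mapped contig records", call. = FALSE)
  rmags <- unique(rmag)
  samps <- unique(contig_records$sample_id)
  rf <- factor(rmag, levels = rmags)
  sf <- factor(contig_records$sample_id, levels = samps)
  num <- stats::xtabs(contig_records$summed_depth ~ rf + sf)
  den <- stats::xtabs(contig_records$length_bp ~ rf + sf)
  out <- matrix(as.numeric(num) / as.numeric(den), nrow(num),
                dimnames = list(rmags, samps))
  out[as.numeric(den) == 0] <- 0
  out
}

#' Genome quality filters
#'
#' `filter_mags()` applies the MAG retention rule: completeness at or above
#' `min_completeness` (default 28%) and contamination strictly below
#' `max_contamination` (default 20%). `select_rmags()` applies the stricter
#' representative-genome rule: completeness minus contamination at least
#' `min_diff` (default 0.50) and a kingdom-level taxonomic assignment present.
#' Both preserve input order and are idempotent.
#'
#' @param quality data.frame as returned by [read_quality_table()].
#' @param min_completeness,max_contamination,min_diff thresholds as fractions.
#' @return character vector of retained mag ids.
#' @export
filter_mags <- function(quality, min_completeness = 0.28,
                        max_contamination = 0.20) {
  keep <- quality$completeness >= min_completeness &
    quality$contamination < max_contamination
  quality$mag_id[keep]
}

#' @rdname filter_mags
#' @export
select_rmags <- function(quality, min_diff = 0.50) {
  keep <- (quality$completeness - quality$contamination) >= min_diff &
    !is.na(quality$kingdom) & nzchar(quality$kingdom)
  quality$mag_id[keep]
}

#' Aggregate a gene-level depth matrix to rMAG depth of coverage
#'
#' Convenience wrapper around [rmag_depth()] for gene x sample depth
#' matrices: converts depth of coverage back to summed per-base depth with
#' the annotated gene lengths and aggregates length-weighted per rMAG.
#'
#' @param depth_mat numeric matrix gene x sample of depth of coverage.
#' @param annotations data.frame with gene_id, rmag_id, length_bp.
#' @return numeric matrix rMAG x sample.
#' @export
rmag_depth_from_gene_matrix <- function(depth_mat, annotations) {
  first <- !duplicated(annotations$gene_id)
  len <- stats::setNames(annotations$length_bp[first],
                         annotations$gene_id[first])
  gl <- unname(len[rownames(depth_mat)])
  rec <- data.frame(
    feature_id = rep(rownames(depth_mat), times = ncol(depth_mat)),
    sample_id = rep(colnames(depth_mat), each = nrow(depth_mat)),
    summed_depth = as.vector(depth_mat) * gl,
    length_bp = gl, stringsAsFactors = FALSE)
  map <- stats::setNames(annotations$rmag_id[first],
                         annotations$gene_id[first])
  rmag_depth(rec, map)
}
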