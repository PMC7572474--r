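#' Pathway-level MT and MP trends by FOAM L1 category
#'
#' Sums gene-level MT depth and MP spectral counts per top-level FOAM
#' category and time-point, divides by the time-point's total over all rMAG
#' genes (annotated or not), min-max scales each category's relative series
#' to `[0, 1]`, and correlates the scaled MT and MP series (Pearson).
#' Genes with several FOAM L1 assignments (repeated annotation rows) count
#' towards each. Categories absent from the MP data keep their MT series but
#' get an `NA` correlation; constant series scale to zeros with a warning.
#' Categories are ordered by mean relative MP count, descending.
#'
#' @param gene_mt_depth numeric matrix gene x time-point of MT depth.
#' @param gene_mp_counts numeric matrix gene x time-point of spectral counts.
#' @param annotations data.frame with gene_id, foam_l1 (possibly repeated
#'   gene rows for multiple categories).
#' @return list with `trends` (long data.frame: foam_l1, timepoint, mt_rel,
#'   mp_rel, mt_scaled, mp_scaled) and `correlations` (foam_l1, r,
#'   mean_mp_rel).
#' @export
foam_trend <- function(gene_mt_depth, gene_mp_counts, annotations) {
  ann <- annotations[!is.na(annotations$foam_l1), c("gene_id", "foam_l1")]
  ann <- unique(ann)
  if (!nrow(ann)) stop("no FOAM L1 annotations", call. = FALSE)
  tps <- colnames(gene_mt_depth)
  tot_mt <- colSums(gene_mt_depth)
  tot_mp <- colSums(gene_mp_counts)
  cats <- sort(unique(ann$foam_l1))
  sum_by_cat <- function(M) {
    out <- matrix(0, length(cats), length(tps),
                  dimnames = list(cats, tps))
    present <- ann$gene_id %in% rownames(M)
    a <- ann[present, ]
    if (nrow(a)) {
      agg <- rowsum(M[a$gene_id, , drop = FALSE], group = a$foam_l1)
      out[rownames(agg), ] <- agg
    }
    out
  }
  mt_rel <- sweep(sum_by_cat(gene_mt_depth), 2, tot_mt, "/")
  mp_rel <- sweep(sum_by_cat(gene_mp_counts), 2,
                  ifelse(tot_mp == 0, NA_real_, tot_mp), "/")
  scale01 <- function(v) {
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[1] == rng[2]) {
      warning("constant series scaled to zeros", call. = FALSE)
      return(v * 0)
    }
    (v - rng[1]) / (rng[2] - rng[1])
  }
  mt_scaled <- t(apply(mt_rel, 1, scale01))
  mp_scaled <- t(apply(mp_rel, 1, scale01))
  r <- vapply(cats, function(cc) {
    a <- mt_scaled[cc, ]; b <- mp_scaled[cc, ]
    if (stats::sd(a) == 0 || is.na(stats::sd(b)) || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  corr <- data.frame(foam_l1 = cats, r = unname(r),
                     mean_mp_rel = rowMeans(mp_rel, na.rm = TRUE),
                     stringsAsFactors = FALSE, row.names = NULL)
  corr <- corr[order(-corr$mean_mp_rel), ]
  rownames(corr) <- NULL
  trends <- data.frame(
    foam_l1 = rep(cats, times = length(tps)),
    timepoint = rep(tps, each = length(cats)),
    mt_rel = as.vector(mt_rel), mp_rel = as.vector(mp_rel),
    mt_scaled = as.vector(mt_scaled), mp_scaled = as.vector(mp_scaled),
    stringsAsFactors = FALSE)
  list(trends = trends, correlations = corr)
}
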