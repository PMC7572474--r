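#' Call KO expression status from MT/MG depth ratios and spectral counts
#'
#' A gene counts as expressed in a sample when either its MT/MG depth ratio
#' exceeds 1, or — for genes whose MG depth is below 1, where the ratio would
#' inflate activity calls for lowly abundant populations — its MT depth
#' itself exceeds 1, or at least 2 peptide spectral counts are assigned to
#' it. A KO of an rMAG is active when at least one of its genes is
#' expressed. The profile covers every (rMAG, KO) with at least one
#' annotated gene; genes absent from a depth table are treated as depth 0
#' and counted in a message.
#'
#' @param gene_mg_depth,gene_mt_depth numeric vectors of gene depth of
#'   coverage at one time-point, named by gene id.
#' @param gene_mp_counts numeric vector of spectral counts, named by gene id
#'   (may be empty).
#' @param annotations data.frame with gene_id, rmag_id, ko_id.
#' @return data.frame with rmag_id, ko_id, active (logical).
#' @export
ko_activity_call <- function(gene_mg_depth, gene_mt_depth,
                             gene_mp_counts = numeric(0), annotations) {
  ann <- unique(annotations[!is.na(annotations$ko_id),
                            c("gene_id", "rmag_id", "ko_id")])
  # genes absent from every depth/count table have depth 0 and can never
  # satisfy the predicate, so the predicate is evaluated on measured genes
  measured_ids <- unique(c(names(gene_mg_depth), names(gene_mt_depth),
                           names(gene_mp_counts)))
  present <- ann$gene_id %in% measured_ids
  n_missing <- sum(!present)
  if (n_missing)
    message(n_missing, " annotated gene(s) missing from the depth tables; ",
            "treated as depth 0")
  g <- ann$gene_id[present]
  lookup <- function(v) {
    x <- v[g]
    x[is.na(x)] <- 0
    x
  }
  mg <- lookup(gene_mg_depth)
  mt <- lookup(gene_mt_depth)
  mp <- if (length(gene_mp_counts)) lookup(gene_mp_counts) else
    numeric(length(g))
  expressed <- gene_expressed(mg, mt, mp)
  key <- paste(ann$rmag_id, ann$ko_id, sep = "\r")
  first <- !duplicated(key)
  active <- key[first] %in% unique(key[present][expressed])
  data.frame(rmag_id = ann$rmag_id[first],
             ko_id = ann$ko_id[first],
             active = active,
             stringsAsFactors = FALSE, row.names = NULL)
}

# The gene-level expression predicate (pure function, vectorised):
# (MG >= 1 and MT/MG > 1) or (MG < 1 and MT > 1) or (MP >= 2).
gene_expressed <- function(mg, mt, mp) {
  (mg >= 1 & mt / mg > 1) | (mg < 1 & mt > 1) | (mp >= 2)
}

#' Convert an activity call table to a binary rMAG x KO matrix
#'
#' @param activity data.frame as from [ko_activity_call()].
#' @param rmag_ids,ko_ids optional row/column universes.
#' @return integer matrix of 0/1 activity status.
#' @export
activity_matrix <- function(activity, rmag_ids = NULL, ko_ids = NULL) {
  rmag_ids <- rmag_ids %||% sort(unique(activity$rmag_id))
  ko_ids <- ko_ids %||% sort(unique(activity$ko_id))
  M <- matrix(0L, length(rmag_ids), length(ko_ids),
              dimnames = list(rmag_ids, ko_ids))
  act <- activity[activity$active, ]
  M[cbind(match(act$rmag_id, rmag_ids), match(act$ko_id, ko_ids))] <- 1L
  M
}

#' Cluster per-time-point expression profiles
#'
#' Binary Jaccard distances between the rMAGs' activity vectors at one
#' time-point, embedded in two dimensions by classical MDS and clustered
#' with HDBSCAN at the given minimum cluster size. Points outside every
#' cluster carry the explicit noise label 0; cluster labels are ordered by
#' descending size.
#'
#' @param activity_mat binary rMAG x KO activity matrix at one time-point.
#' @param min_cluster_size minimum members per cluster (default 5).
#' @return list with `cluster` (named integer vector, 0 = noise),
#'   `n_clusters`, `embedding`.
#' @export
cluster_expression_profiles <- function(activity_mat, min_cluster_size = 5) {
  n <- nrow(activity_mat)
  if (n < min_cluster_size)
    return(list(cluster = stats::setNames(rep(0L, n),
                                          rownames(activity_mat)),
                n_clusters = 0L, embedding = NULL))
  D <- suppressWarnings(jaccard_distances(activity_mat))
  if (all(D == 0)) {
    # all profiles identical: a single cluster
    return(list(cluster = stats::setNames(rep(1L, n),
                                          rownames(activity_mat)),
                n_clusters = 1L, embedding = NULL))
  }
  emb <- suppressWarnings(classical_mds(D, 2))
  fit <- hdbscan_cluster(emb, min_cluster_size = min_cluster_size)
  list(cluster = fit$cluster, n_clusters = fit$n_clusters, embedding = emb)
}

#' MT/MG depth ratios per rMAG, summarised by condition and group
#'
#' The per-sample activity proxy of an rMAG is its MT depth divided by its
#' MG depth; samples with MG depth 0 are excluded (and counted). Ratios are
#' averaged over the samples of each condition, and summarised (median,
#' quartiles) over the rMAGs of each group (functional cluster or taxon).
#'
#' @param rmag_mg,rmag_mt numeric matrices rMAG x sample of depth of
#'   coverage.
#' @param grouping named vector mapping rMAG id to a group label.
#' @param conditions named vector mapping sample id to a condition label.
#' @return list with `per_rmag` (rmag_id, condition, mean_ratio, n_samples)
#'   and `per_group` (group, condition, median, q25, q75, n).
#' @export
mtmg_ratio <- function(rmag_mg, rmag_mt, grouping, conditions) {
  stopifnot(identical(dim(rmag_mg), dim(rmag_mt)))
  samples <- colnames(rmag_mg)
  ratio <- rmag_mt / rmag_mg
  undefined <- !is.finite(ratio)
  if (any(undefined))
    message(sum(undefined), " rMAG/sample ratio(s) undefined (MG depth 0) ",
            "and excluded")
  ratio[undefined] <- NA_real_
  cond <- conditions[samples]
  per_rmag <- do.call(rbind, lapply(unique(cond), function(cc) {
    cols <- which(cond == cc)
    data.frame(rmag_id = rownames(ratio), condition = cc,
               mean_ratio = rowMeans(ratio[, cols, drop = FALSE],
                                     na.rm = TRUE),
               n_samples = rowSums(!is.na(ratio[, cols, drop = FALSE])),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_rmag$group <- unname(grouping[per_rmag$rmag_id])
  per_group <- do.call(rbind, lapply(
    split(per_rmag, list(per_rmag$group, per_rmag$condition), drop = TRUE),
    function(d) data.frame(group = d$group[1], condition = d$condition[1],
                           median = stats::median(d$mean_ratio, na.rm = TRUE),
                           q25 = unname(stats::quantile(d$mean_ratio, 0.25,
                                                        na.rm = TRUE)),
                           q75 = unname(stats::quantile(d$mean_ratio, 0.75,
                                                        na.rm = TRUE)),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_rmag = per_rmag, per_group = per_group)
}

#' How often a KO is active while a focal rMAG is co-clustered
#'
#' Counts the time-points at which `ko_id` is active in the focal rMAG's
#' expression profile while the focal rMAG belongs to a non-noise expression
#' cluster. Also reports, per co-clustered rMAG, the number of those
#' time-points at which the KO was active in that rMAG (activity frequency
#' among co-clustered populations).
#'
#' @param clusters named list (by time-point) of cluster label vectors, as
#'   produced by [cluster_expression_profiles()] over time.
#' @param activities named list (by time-point) of activity matrices.
#' @param focal_rmag rMAG id of interest.
#' @param ko_id KO id of interest.
#' @return list with `count` (integer) and `companions` (data.frame rmag_id,
#'   n_active, n_cocluster).
#' @export
cluster_ko_frequency <- function(clusters, activities, focal_rmag, ko_id) {
  tps <- names(clusters)
  count <- 0L
  comp_active <- list(); comp_seen <- list()
  clustered_any <- FALSE
  for (tp in tps) {
    cl <- clusters[[tp]]
    A <- activities[[tp]]
    if (!(focal_rmag %in% names(cl)) || cl[focal_rmag] == 0L) next
    clustered_any <- TRUE
    mates <- setdiff(names(cl)[cl == cl[focal_rmag]], focal_rmag)
    active_here <- ko_id %in% colnames(A) &&
      focal_rmag %in% rownames(A) && A[focal_rmag, ko_id] == 1L
    if (active_here) count <- count + 1L
    for (m in mates) {
      comp_seen[[m]] <- (comp_seen[[m]] %||% 0L) + 1L
      m_active <- ko_id %in% colnames(A) && m %in% rownames(A) &&
        A[m, ko_id] == 1L
      comp_active[[m]] <- (comp_active[[m]] %||% 0L) + as.integer(m_active)
    }
  }
  if (!clustered_any)
    warning("focal rMAG ", focal_rmag, " is noise at every time-point",
            call. = FALSE)
  companions <- if (length(comp_seen))
    data.frame(rmag_id = names(comp_seen),
               n_active = unlist(comp_active[names(comp_seen)]),
               n_cocluster = unlist(comp_seen),
               stringsAsFactors = FALSE, row.names = NULL)
  else data.frame(rmag_id = character(), n_active = integer(),
                  n_cocluster = integer())
  list(count = count, companions = companions)
}
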