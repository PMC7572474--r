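#' Build the binary KO presence/absence matrix
#'
#' Each cell is 1 when the rMAG carries at least one gene annotated with the
#' KEGG ortholog group, 0 otherwise. Columns are the sorted union of KO ids
#' seen in the annotations; rows follow `rmag_ids`.
#'
#' @param annotations data.frame as from [read_annotations()].
#' @param rmag_ids character vector of rMAGs to include (must all occur in
#'   the annotations).
#' @return integer matrix rMAG x KO with values in \{0, 1\}.
#' @export
build_ko_presence <- function(annotations, rmag_ids) {
  if (!nrow(annotations)) stop("empty annotation set", call. = FALSE)
  if (!all(rmag_ids %in% annotations$rmag_id))
    stop("rmag_ids absent from annotations: ",
         paste(setdiff(rmag_ids, annotations$rmag_id), collapse = ", "),
         call. = FALSE)
  ann <- annotations[!is.na(annotations$ko_id) &
                       annotations$rmag_id %in% rmag_ids, ]
  kos <- sort(unique(ann$ko_id))
  M <- matrix(0L, length(rmag_ids), length(kos),
              dimnames = list(rmag_ids, kos))
  M[cbind(match(ann$rmag_id, rmag_ids), match(ann$ko_id, kos))] <- 1L
  M
}

#' Pairwise binary Jaccard distances
#'
#' `d(a, b) = 1 - |a AND b| / |a OR b|` over the rows of a binary matrix.
#' A pair of all-zero rows has an undefined (0/0) Jaccard distance; it is
#' reported as 0 with a warning.
#'
#' @param M binary matrix (rows are observations).
#' @return symmetric distance matrix with zero diagonal, values in `[0, 1]`.
#' @export
jaccard_distances <- function(M) {
  if (nrow(M) < 2) stop("need at least two rows", call. = FALSE)
  M <- (M != 0) * 1
  inter <- tcrossprod(M)
  size <- rowSums(M)
  uni <- outer(size, size, `+`) - inter
  D <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("all-zero row pair(s): Jaccard distance undefined, reported as 0",
            call. = FALSE)
    D[uni == 0] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Eigendecomposition of the double-centred `-D^2/2` matrix; coordinates are
#' taken from the top `dims` positive eigenvalues, ordered by eigenvalue.
#' The proportion of variance explained by each returned axis (eigenvalue
#' over the sum of positive eigenvalues) is attached as attribute
#' `"variance_explained"`. If fewer than `dims` positive eigenvalues exist,
#' the remaining coordinates are zero-padded with a warning.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dims number of output dimensions (default 2).
#' @return numeric matrix n x dims with rownames of `D`.
#' @export
classical_mds <- function(D, dims = 2) {
  check_dist_matrix(D)
  n <- nrow(D)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(dims, n - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  npos <- min(length(pos), dims)
  X <- matrix(0, n, dims, dimnames = list(rownames(D), paste0("MDS", 1:dims)))
  if (npos < dims)
    warning("only ", npos, " positive eigenvalue(s); padding with zeros",
            call. = FALSE)
  if (npos > 0) X[, seq_len(npos)] <- fit$points[, seq_len(npos), drop = FALSE]
  ve <- rep(0, dims)
  if (length(pos)) ve[seq_len(npos)] <- pos[seq_len(npos)] / sum(pos)
  attr(X, "variance_explained") <- ve
  X
}

# k-means++ seeding followed by stats::kmeans, best of `nstart` restarts.
# Degenerate inputs (fewer distinct points than k) fall back to assigning
# each distinct location its own cluster (within-SS 0 beyond them).
kmeans_pp <- function(X, k, nstart = 25) {
  n <- nrow(X)
  ux <- unique(X)
  if (nrow(ux) <= k) {
    key <- apply(X, 1, paste, collapse = "\r")
    cl <- match(key, unique(key))
    centers <- ux[seq_len(max(cl)), , drop = FALSE]
    ss <- sum((X - centers[cl, , drop = FALSE])^2)
    return(list(cluster = cl, centers = centers, tot.withinss = ss))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
      for (j in 2:k) {
        probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
        d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                           byrow = TRUE))^2))
      }
    }
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Choose the number of clusters by the elbow of the within-SS curve
#'
#' Runs k-means (k-means++ seeding, 25 restarts) for each `k` in `k_range`
#' and records the total within-cluster sum of squares. The elbow is the `k`
#' with maximum perpendicular distance to the chord joining the curve's two
#' endpoints (the "kneedle" rule). A flat or non-decreasing curve returns the
#' smallest `k` with a warning. `k_override` bypasses the rule.
#'
#' @param embedding numeric matrix of coordinates.
#' @param k_range candidate numbers of centroids (default 1..9).
#' @param seed integer RNG seed.
#' @param k_override optional manual choice of `k`.
#' @return list with `k` and `withinss` (named numeric curve over `k_range`).
#' @export
choose_k_elbow <- function(embedding, k_range = 1:9, seed = 1,
                           k_override = NULL) {
  if (max(k_range) > nrow(embedding) - 1)
    k_range <- k_range[k_range <= nrow(embedding) - 1]
  ss <- with_seed(seed, vapply(
    k_range, function(k) kmeans_pp(embedding, k)$tot.withinss, numeric(1)))
  names(ss) <- k_range
  if (!is.null(k_override))
    return(list(k = as.integer(k_override), withinss = ss))
  k <- kneedle_k(k_range, ss)
  list(k = k, withinss = ss)
}

# Maximum perpendicular distance to the chord between the curve endpoints.
kneedle_k <- function(k_range, ss) {
  if (all(diff(ss) >= 0) || all(ss < 1e-12)) {
    warning("within-SS curve has no elbow; returning smallest k",
            call. = FALSE)
    return(as.integer(k_range[1]))
  }
  x1 <- k_range[1]; y1 <- ss[1]
  x2 <- k_range[length(k_range)]; y2 <- ss[length(ss)]
  # distance from (k, ss) to the line through (x1,y1)-(x2,y2)
  d <- abs((y2 - y1) * k_range - (x2 - x1) * ss + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  as.integer(k_range[which.max(d)])
}

#' Assign rMAGs to functional clusters by k-means
#'
#' k-means with k-means++ seeding and 25 restarts on the 2-D embedding; the
#' restart with the lowest total within-SS wins. Cluster labels are renumbered
#' 1..k by descending cluster size (ties by first occurrence).
#'
#' @param embedding numeric matrix of coordinates (rownames = rMAG ids).
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @return list with `cluster` (named integer vector), `k`, `centers`,
#'   `tot_withinss`.
#' @export
kmeans_assign <- function(embedding, k, seed = 1) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(embedding)) stop("k exceeds number of points", call. = FALSE)
  fit <- with_seed(seed, kmeans_pp(embedding, k))
  sizes <- tabulate(fit$cluster, k)
  relabel <- order(order(-sizes))  # old label -> new label by descending size
  cl <- relabel[fit$cluster]
  names(cl) <- rownames(embedding)
  list(cluster = cl, k = k,
       centers = fit$centers[order(-sizes), , drop = FALSE],
       tot_withinss = fit$tot.withinss)
}

#' KO set overlaps between functional clusters
#'
#' For each cluster, the union of its members' KO sets; and for every
#' non-empty subset of clusters, the number of KOs present in exactly those
#' clusters (the UpSet partition of the global KO union).
#'
#' @param M binary KO presence matrix.
#' @param cluster named integer vector of cluster labels covering all rows.
#' @return list with `union_sizes` (named by cluster) and `regions`
#'   (data.frame: subset label such as `"1&3"`, count).
#' @export
ko_set_overlaps <- function(M, cluster) {
  cluster <- cluster[rownames(M)]
  if (any(is.na(cluster))) stop("cluster labels must cover all rows",
                                call. = FALSE)
  ks <- sort(unique(cluster))
  present <- vapply(ks, function(g)
    colSums(M[cluster == g, , drop = FALSE] != 0) > 0,
    logical(ncol(M)))  # KO x cluster
  colnames(present) <- ks
  union_sizes <- colSums(present)
  anywhere <- rowSums(present) > 0
  sig <- apply(present[anywhere, , drop = FALSE], 1, function(v)
    paste(ks[v], collapse = "&"))
  tab <- table(sig)
  regions <- data.frame(subset = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(union_sizes = union_sizes, regions = regions)
}

#' One-sided Fisher enrichment of KOs within clusters
#'
#' For every (KO, cluster) pair, tests over-representation of the KO among
#' the cluster's rMAGs against all other rMAGs with the one-sided
#' hypergeometric tail, then adjusts across all pairs with Benjamini-Hochberg.
#' A pair is enriched when the adjusted p-value is below `alpha`.
#'
#' @param M binary KO presence matrix.
#' @param cluster named integer vector of cluster labels.
#' @param alpha enrichment threshold on adjusted p-values (default 0.05).
#' @return data.frame with ko_id, cluster, the 2x2 counts (`in_with`,
#'   `in_without`, `out_with`, `out_without`), `p`, `p_adj`, `enriched`.
#' @export
fisher_enrichment <- function(M, cluster, alpha = 0.05) {
  cluster <- cluster[rownames(M)]
  ks <- sort(unique(cluster))
  if (length(ks) < 2) stop("need at least two clusters", call. = FALSE)
  n <- nrow(M)
  res <- lapply(ks, function(g) {
    ing <- cluster == g
    ng <- sum(ing)
    with_ko <- colSums(M != 0)            # total rMAGs carrying the KO
    in_with <- colSums(M[ing, , drop = FALSE] != 0)
    p <- stats::phyper(in_with - 1, with_ko, n - with_ko, ng,
                       lower.tail = FALSE)
    p[with_ko == 0] <- 1                  # KO absent everywhere
    data.frame(ko_id = colnames(M), cluster = g,
               in_with = in_with, in_without = ng - in_with,
               out_with = with_ko - in_with,
               out_without = (n - ng) - (with_ko - in_with),
               p = pmin(p, 1), stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adj < alpha
  out
}

#' Completeness-adjusted prevalence of a KO set within clusters
#'
#' The proportion of a cluster's rMAGs carrying at least one KO of `ko_set`,
#' divided by the cluster's mean genome completeness and capped at 1. This
#' corrects raw prevalence for pathway genes missed in incomplete genomes.
#'
#' @param M binary KO presence matrix.
#' @param cluster named integer vector of cluster labels.
#' @param quality data.frame with mag_id and completeness (fractions).
#' @param ko_set character vector of KO ids defining the function.
#' @return named numeric vector of adjusted prevalences per cluster.
#' @export
adjusted_prevalence <- function(M, cluster, quality, ko_set) {
  cluster <- cluster[rownames(M)]
  comp <- quality$completeness[match(rownames(M), quality$mag_id)]
  if (any(is.na(comp)))
    stop("completeness missing for some rMAGs", call. = FALSE)
  kos <- intersect(ko_set, colnames(M))
  carrier <- if (length(kos))
    rowSums(M[, kos, drop = FALSE] != 0) > 0 else rep(FALSE, nrow(M))
  vapply(sort(unique(cluster)), function(g) {
    mc <- mean(comp[cluster == g])
    if (mc == 0) stop("mean completeness of cluster ", g, " is 0",
                      call. = FALSE)
    min(1, mean(carrier[cluster == g]) / mc)
  }, numeric(1))
}

#' Procrustes superimposition and PROTEST permutation test
#'
#' Least-squares Procrustes with translation, rotation/reflection and
#' scaling under the symmetric convention: both configurations are centred
#' and scaled to unit sum of squares, so the minimised residual sum of
#' squares `m2` lies in `[0, 1]` and the Procrustes correlation is
#' `sqrt(1 - m2)`. Significance is assessed by permuting the rows of `Y`
#' (`p = (#{m2_perm <= m2_obs} + 1) / (n_perm + 1)`).
#'
#' @param X,Y numeric matrices with identical rownames (target, rotated).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer RNG seed.
#' @return list with `m2`, `correlation`, `p`, `n_perm`.
#' @export
procrustes_protest <- function(X, Y, n_perm = 9999, seed = 1) {
  if (nrow(X) < 3) stop("need at least three rows", call. = FALSE)
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !setequal(rownames(X), rownames(Y)))
    stop("X and Y must share row ids", call. = FALSE)
  Y <- Y[rownames(X), , drop = FALSE]
  m2_obs <- procrustes_m2(X, Y)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    procrustes_m2(X, Y[sample.int(nrow(Y)), , drop = FALSE]), numeric(1)))
  p <- (sum(perm <= m2_obs) + 1) / (n_perm + 1)
  list(m2 = m2_obs, correlation = sqrt(max(0, 1 - m2_obs)), p = p,
       n_perm = n_perm)
}

# Symmetric Procrustes residual: both matrices centred and trace-normalised;
# m2 = 1 - (sum of singular values of X'Y)^2.
procrustes_m2 <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  d <- svd(crossprod(X, Y))$d
  max(0, 1 - sum(d)^2)
}
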