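# Hierarchical density-based clustering (HDBSCAN) on a small point set or
# distance matrix. Steps: core distances -> mutual reachability distances ->
# single-linkage hierarchy (equivalent to the minimum spanning tree of the
# mutual reachability graph) -> condensed cluster tree at the given minimum
# cluster size -> excess-of-mass cluster selection -> point labels with an
# explicit noise label (0).

#' Density-based clustering with noise (HDBSCAN)
#'
#' @param x numeric matrix of coordinates, or a symmetric distance matrix
#'   when `is_dist = TRUE`.
#' @param min_cluster_size minimum members per cluster; also used as the
#'   `min_samples` smoothing parameter for core distances.
#' @param is_dist interpret `x` as a distance matrix.
#' @return list with `cluster` (integer labels, 0 = noise, clusters numbered
#'   by descending size) and `n_clusters`.
#' @export
hdbscan_cluster <- function(x, min_cluster_size = 5, is_dist = FALSE) {
  D <- if (is_dist) as.matrix(x) else as.matrix(stats::dist(x))
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (n < min_cluster_size)
    return(list(cluster = stats::setNames(rep(0L, n), ids), n_clusters = 0L))
  # core distance: distance to the (min_samples - 1)-th nearest neighbour
  # (the point itself counts towards min_samples)
  k <- min(min_cluster_size - 1L, n - 1L)
  core <- apply(D, 1, function(d) sort(d)[k + 1L])
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0
  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  labels <- condense_and_select(hc, n, min_cluster_size)
  sizes <- tabulate(labels, max(c(labels, 1L)))
  keep <- which(sizes > 0)
  relabel <- integer(max(c(labels, 1L)))
  relabel[keep[order(-sizes[keep])]] <- seq_along(keep)
  out <- ifelse(labels == 0L, 0L, relabel[pmax(labels, 1L)])
  list(cluster = stats::setNames(as.integer(out), ids),
       n_clusters = length(keep))
}

# Build the condensed tree from a single-linkage hclust object and select
# clusters by stability (excess of mass); returns raw integer labels
# (0 = noise).
condense_and_select <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- pmax(hc$height, 1e-12)
  nm <- nrow(merge)
  if (nm == 0) return(rep(1L, n))
  # members of each merge node
  members <- vector("list", nm)
  node_members <- function(id) {
    if (id < 0) -id else members[[id]]
  }
  for (i in seq_len(nm))
    members[[i]] <- c(node_members(merge[i, 1]), node_members(merge[i, 2]))

  # condensed tree accumulators
  cl_parent <- integer(0)     # parent condensed cluster id (0 = none)
  cl_birth <- numeric(0)      # lambda at which the cluster is born
  cl_stab <- numeric(0)       # accumulated stability
  cl_children <- list()       # child condensed cluster ids
  pt_cluster <- integer(n)    # condensed cluster each point falls out of
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_birth)]] <<- integer(0)
    if (parent > 0)
      cl_children[[parent]] <<- c(cl_children[[parent]], length(cl_birth))
    length(cl_birth)
  }

  # walk the merge tree from the root; each hclust node is processed with
  # the condensed cluster it currently belongs to
  root_cl <- new_cluster(0L, 1 / height[nm])
  stack <- list(list(node = nm, cl = root_cl))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    lambda <- 1 / height[node]
    kids <- merge[node, ]
    sizes <- vapply(kids, function(id) if (id < 0) 1L else length(members[[id]]),
                    integer(1))
    big <- sizes >= mcs
    if (all(big)) {
      # true split: both children become new condensed clusters
      cl_stab[cl] <- cl_stab[cl] + sum(sizes) * (lambda - cl_birth[cl])
      for (j in 1:2) {
        child_cl <- new_cluster(cl, lambda)
        stack[[length(stack) + 1L]] <- list(node = kids[j], cl = child_cl)
      }
    } else {
      # points of undersized children fall out of `cl` at this lambda
      for (j in 1:2) {
        pts_j <- if (kids[j] < 0) -kids[j] else members[[kids[j]]]
        if (!big[j] || kids[j] < 0) {
          cl_stab[cl] <- cl_stab[cl] + sizes[j] * (lambda - cl_birth[cl])
          pt_cluster[pts_j] <- cl
        } else {
          stack[[length(stack) + 1L]] <- list(node = kids[j], cl = cl)
        }
      }
    }
  }

  n_cl <- length(cl_birth)
  # excess-of-mass selection, bottom-up (children have larger ids)
  score <- cl_stab
  selected <- rep(TRUE, n_cl)
  for (cl in rev(seq_len(n_cl))) {
    ch <- cl_children[[cl]]
    if (!length(ch)) next
    child_score <- sum(score[ch])
    if (cl == 1L && n_cl > 1L) {
      # the root is not a selectable cluster once it has split
      selected[cl] <- FALSE
      score[cl] <- child_score
    } else if (child_score > score[cl]) {
      selected[cl] <- FALSE
      score[cl] <- child_score
    } else {
      # deselect all descendants
      desc <- ch
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(cl_children[desc])
      }
    }
  }

  # a point belongs to the selected ancestor-or-self of its fall-out cluster
  sel_anc <- integer(n_cl)
  for (cl in seq_len(n_cl)) {
    cur <- cl
    while (cur > 0 && !selected[cur]) cur <- cl_parent[cur]
    sel_anc[cl] <- cur
  }
  sel_anc[pt_cluster]
}
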