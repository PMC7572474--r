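# Brute-force reference implementations, deliberately written as plain
# double loops / set arithmetic so they share no code with the package.

oracle_jaccard <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(M[i, ] != 0); b <- which(M[j, ] != 0)
    u <- length(union(a, b))
    D[i, j] <- if (u == 0) 0 else 1 - length(intersect(a, b)) / u
  }
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

oracle_braycurtis <- function(X) {
  # columns are samples
  n <- ncol(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(X))) {
      num <- num + abs(X[k, i] - X[k, j])
      den <- den + X[k, i] + X[k, j]
    }
    D[i, j] <- num / den
  }
  D
}

oracle_permanova_partition <- function(D, groups) {
  n <- nrow(D)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + D[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
    ss_within <- ss_within + s / length(idx)
  }
  list(ss_total = ss_total, ss_within = ss_within,
       R2 = 1 - ss_within / ss_total)
}

oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

oracle_bh <- function(p) {
  # step-up procedure written out longhand
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

oracle_overlap_partition <- function(sets) {
  # sets: named list of character vectors; returns counts per exact region
  all_items <- unique(unlist(sets))
  sig <- vapply(all_items, function(it)
    paste(names(sets)[vapply(sets, function(s) it %in% s, logical(1))],
          collapse = "&"), character(1))
  table(sig)
}

oracle_weighted_depth <- function(records, map) {
  # length-weighted mean coverage per (rMAG, sample), triple loop
  rmags <- sort(unique(map[records$feature_id]))
  samples <- sort(unique(records$sample_id))
  out <- matrix(0, length(rmags), length(samples),
                dimnames = list(rmags, samples))
  for (r in rmags) for (s in samples) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(records))) {
      if (identical(unname(map[records$feature_id[k]]), r) &&
          records$sample_id[k] == s) {
        num <- num + records$summed_depth[k]
        den <- den + records$length_bp[k]
      }
    }
    if (den > 0) out[r, s] <- num / den
  }
  out
}

# Random binary matrix with informative margins
random_binary_matrix <- function(n, m, p = 0.4) {
  matrix(as.integer(stats::runif(n * m) < p), n, m,
         dimnames = list(paste0("r", seq_len(n)), paste0("k", seq_len(m))))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
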