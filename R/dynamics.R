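#' Relative abundance profiles from rMAG depth of coverage
#'
#' Divides each time-point (column) by its column sum, so abundances sum to 1
#' per time-point.
#'
#' @param rmag_depths numeric matrix rMAG x sample of depth of coverage.
#' @return matrix of the same shape with unit column sums.
#' @export
relative_abundance <- function(rmag_depths) {
  if (any(rmag_depths < 0)) stop("depths must be non-negative", call. = FALSE)
  cs <- colSums(rmag_depths)
  if (any(cs == 0))
    stop("all-zero time-point(s): ",
         paste(colnames(rmag_depths)[cs == 0], collapse = ", "),
         call. = FALSE)
  sweep(rmag_depths, 2, cs, "/")
}

#' Correlation-based distances between abundance profiles
#'
#' Pairwise correlation `rho` between the rows, transformed to a distance by
#' `d = 1 - (rho + 1) / 2`, so perfectly correlated profiles are at distance
#' 0, anti-correlated ones at distance 1 and uncorrelated ones at 0.5.
#' A constant profile has no defined correlation; its distances are recorded
#' as `NA` with a warning.
#'
#' @param profiles numeric matrix (rows = rMAGs, columns = time-points).
#' @param method correlation method (default `"pearson"`).
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(profiles, method = "pearson") {
  if (ncol(profiles) < 3) stop("need at least three time-points",
                               call. = FALSE)
  constant <- apply(profiles, 1, stats::sd) == 0
  if (any(constant))
    warning("constant profile(s): ",
            paste(rownames(profiles)[constant], collapse = ", "),
            "; their distances are NA", call. = FALSE)
  rho <- suppressWarnings(stats::cor(t(profiles), method = method))
  D <- 1 - (rho + 1) / 2
  diag(D) <- 0
  D
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor partition of the squared inter-point distances:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed per group with the
#' group size as divisor, `R^2 = 1 - SS_within / SS_total`, and the pseudo-F
#' statistic `(SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value
#' comes from permuting group labels, with the add-one convention
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' @param D symmetric distance matrix.
#' @param groups group labels (length `nrow(D)`, at least 2 groups of >= 2).
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return list with `pseudo_F`, `R2`, `p`, `SS_total`, `SS_within`,
#'   `SS_between`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1) {
  check_dist_matrix(D)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least two members",
                         call. = FALSE)
  n <- nrow(D)
  a <- length(tab)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within_fun <- function(g) {
    sum(vapply(unique(g), function(lev) {
      i <- which(g == lev)
      sum(D2[i, i][upper.tri(D2[i, i, drop = FALSE])]) / length(i)
    }, numeric(1)))
  }
  f_stat <- function(ssw) ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  ssw_obs <- ss_within_fun(groups)
  F_obs <- if (ssw_obs == 0) Inf else f_stat(ssw_obs)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    ssw <- ss_within_fun(g)
    if (ssw == 0) Inf else f_stat(ssw)
  }, numeric(1)))
  p <- (sum(perm >= F_obs) + 1) / (n_perm + 1)
  list(pseudo_F = F_obs, R2 = 1 - ssw_obs / ss_total, p = p,
       SS_total = ss_total, SS_within = ssw_obs,
       SS_between = ss_total - ssw_obs, n_perm = n_perm)
}

#' Homogeneity of multivariate dispersion
#'
#' Embeds the distance matrix by classical MDS retaining all
#' positive-eigenvalue axes, computes every point's Euclidean distance to its
#' group centroid, and tests equality of mean dispersion between groups with
#' a one-way F statistic whose null distribution is obtained by permuting
#' group labels.
#'
#' @inheritParams permanova
#' @return list with `group_means` (mean distance to centroid per group),
#'   `F`, `p`, `distances` (per point), `n_perm`.
#' @export
dispersion_test <- function(D, groups, n_perm = 999, seed = 1) {
  check_dist_matrix(D)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least two members",
                         call. = FALSE)
  n <- nrow(D)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  keep <- fit$eig[seq_len(ncol(fit$points))] > 1e-12
  X <- fit$points[, keep, drop = FALSE]
  dist_to_centroid <- function(g) {
    d <- numeric(n)
    for (lev in unique(g)) {
      i <- which(g == lev)
      cen <- colMeans(X[i, , drop = FALSE])
      d[i] <- sqrt(rowSums((X[i, , drop = FALSE] -
                              matrix(cen, length(i), ncol(X),
                                     byrow = TRUE))^2))
    }
    d
  }
  anova_F <- function(z, g) {
    gm <- tapply(z, g, mean)
    ng <- tapply(z, g, length)
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[g])^2)
    a <- length(gm)
    if (ssw == 0) return(Inf)
    (ssb / (a - 1)) / (ssw / (length(z) - a))
  }
  z <- dist_to_centroid(groups)
  F_obs <- anova_F(z, groups)
  # permute which points carry which label; distances are recomputed to the
  # permuted groups' centroids, as in distance-based dispersion tests
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    anova_F(z[idx], groups)
  }, numeric(1)))
  p <- (sum(perm >= F_obs) + 1) / (n_perm + 1)
  list(group_means = tapply(z, groups, mean), F = F_obs, p = p,
       distances = stats::setNames(z, rownames(D)), n_perm = n_perm)
}

#' Temporal stability of abundance profiles
#'
#' Stability of a population is the mean over standard deviation (sample
#' s.d.) of its relative-abundance series over the included time-points;
#' higher values mean a more constant population. `exclude_window` removes
#' the listed time-points (e.g. a disturbance period) before computing.
#' Zero-variance series get `NA` stability and are flagged.
#'
#' @param profiles numeric matrix rMAG x time-point of relative abundances.
#' @param exclude_window character vector of time-point (column) names to
#'   exclude, or `NULL` for the full series.
#' @return data.frame with rmag_id, stability, undefined flag and the number
#'   of time-points used.
#' @export
temporal_stability <- function(profiles, exclude_window = NULL) {
  keep <- setdiff(colnames(profiles), exclude_window)
  if (length(keep) < 2)
    stop("need at least two time-points after exclusion", call. = FALSE)
  P <- profiles[, keep, drop = FALSE]
  m <- rowMeans(P)
  s <- apply(P, 1, stats::sd)
  stab <- ifelse(s == 0, NA_real_, m / s)
  data.frame(rmag_id = rownames(profiles), stability = stab,
             undefined = s == 0, n_timepoints = length(keep),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarities and their principal-coordinate ordination
#'
#' `BC(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` between sample columns,
#' followed by classical MDS of the resulting distance matrix.
#'
#' @param abundances numeric matrix (rows = taxa, columns = samples) of
#'   non-negative values.
#' @param dims ordination dimensionality (default 2).
#' @return list with `D` (sample x sample Bray-Curtis matrix) and
#'   `embedding` (samples x dims).
#' @export
braycurtis_pcoa <- function(abundances, dims = 2) {
  if (any(abundances < 0)) stop("abundances must be non-negative",
                                call. = FALSE)
  if (any(colSums(abundances) == 0))
    stop("all-zero sample(s): Bray-Curtis undefined", call. = FALSE)
  n <- ncol(abundances)
  D <- matrix(0, n, n, dimnames = list(colnames(abundances),
                                       colnames(abundances)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- abundances[, i]; b <- abundances[, j]
    D[i, j] <- D[j, i] <- sum(abs(a - b)) / sum(a + b)
  }
  list(D = D, embedding = classical_mds(D, dims))
}

#' Fit abiotic factors onto an ordination
#'
#' For every abiotic factor, z-scores the factor, drops time-points with
#' missing values pairwise, regresses the factor on the ordination axes by
#' least squares, and reports the arrow (unit coefficient vector scaled by
#' `sqrt(R^2)`), the `R^2`, and a permutation p-value on `R^2`. Constant
#' factors are skipped with a warning.
#'
#' @param embedding samples x 2 ordination coordinates.
#' @param abiotic numeric matrix or data.frame, samples x factors (rownames
#'   must match the embedding's).
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return data.frame with factor, arrow1, arrow2, R2, p, n_used.
#' @export
fit_factors <- function(embedding, abiotic, n_perm = 999, seed = 1) {
  abiotic <- as.matrix(abiotic)
  stopifnot(!is.null(rownames(embedding)), !is.null(rownames(abiotic)))
  res <- list()
  for (f in colnames(abiotic)) {
    v <- abiotic[, f]
    ok <- !is.na(v) & rownames(abiotic) %in% rownames(embedding)
    ids <- rownames(abiotic)[ok]
    if (length(ids) < 3 || stats::sd(v[ok]) == 0) {
      warning("factor ", f, " skipped (constant or too few observations)",
              call. = FALSE)
      next
    }
    y <- as.numeric(zscore(v[ok]))
    X <- scale(embedding[ids, , drop = FALSE], center = TRUE, scale = FALSE)
    r2_of <- function(yy) {
      fit <- stats::lm.fit(X, yy - mean(yy))
      1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
    }
    fit <- stats::lm.fit(X, y)
    b <- fit$coefficients
    r2 <- r2_of(y)
    arrow <- if (sqrt(sum(b^2)) > 0) b / sqrt(sum(b^2)) * sqrt(max(0, r2))
      else b * 0
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      r2_of(y[sample.int(length(y))]), numeric(1)))
    p <- (sum(perm >= r2) + 1) / (n_perm + 1)
    res[[f]] <- data.frame(factor = f, arrow1 = arrow[1], arrow2 = arrow[2],
                           R2 = r2, p = p, n_used = length(y),
                           stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(factor = character(), arrow1 = numeric(),
                      arrow2 = numeric(), R2 = numeric(), p = numeric(),
                      n_used = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spearman associations between abundances and abiotic factors
#'
#' Spearman's rank correlation (tie-corrected) between every rMAG abundance
#' series and every abiotic factor over pairwise-complete observations, with
#' Benjamini-Hochberg adjustment across all pairs. Pairs with fewer than
#' `min_pairs` complete observations are skipped and logged.
#'
#' @param abundances matrix rMAG x time-point.
#' @param abiotic matrix or data.frame time-point x factor (rownames matching
#'   the abundance columns).
#' @param min_pairs minimum paired observations per test (default 5).
#' @param adjust apply BH adjustment (default TRUE).
#' @return data.frame with rmag_id, factor, rho, p, p_adj.
#' @export
spearman_associations <- function(abundances, abiotic, min_pairs = 5,
                                  adjust = TRUE) {
  abiotic <- as.matrix(abiotic)
  common <- intersect(colnames(abundances), rownames(abiotic))
  rows <- list()
  skipped <- 0L
  for (r in rownames(abundances)) for (f in colnames(abiotic)) {
    x <- abundances[r, common]
    y <- abiotic[common, f]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) { skipped <- skipped + 1L; next }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rows[[paste(r, f)]] <- data.frame(
      rmag_id = r, factor = f, rho = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " pair(s) skipped (fewer than ", min_pairs,
                       " complete observations)")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- if (adjust) stats::p.adjust(out$p, "BH") else out$p
  out
}

#' z-score transformation
#'
#' `(x - mean) / sd` with the sample standard deviation, computed over
#' non-missing values; missing values are preserved. A constant vector maps
#' to all zeros with a warning.
#'
#' @param values numeric vector.
#' @return numeric vector of the same length.
#' @export
zscore <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning("constant input: z-scores set to 0", call. = FALSE)
    out <- ifelse(is.na(values), NA_real_, 0)
    return(out)
  }
  (values - m) / s
}

#' Stineman interpolation of gaps in a series
#'
#' Fills interior missing values with the Stineman (1980) rational
#' interpolant using circle-based slope estimates: exact on linear segments,
#' and monotone (no overshoot) between monotone knots. Leading or trailing
#' gaps are filled with the nearest observed value, with a warning.
#'
#' @param x positions (numeric, strictly increasing); defaults to the index.
#' @param y values with `NA` gaps; at least two observed points required.
#' @return numeric vector with all gaps filled.
#' @export
stineman_impute <- function(y, x = seq_along(y)) {
  obs <- which(!is.na(y))
  if (length(obs) < 2) stop("need at least two observed points",
                            call. = FALSE)
  out <- y
  if (obs[1] > 1 || obs[length(obs)] < length(y)) {
    warning("leading/trailing gaps filled with nearest observed value",
            call. = FALSE)
    out[seq_len(obs[1])] <- y[obs[1]]
    out[obs[length(obs)]:length(y)] <- y[obs[length(obs)]]
  }
  xi <- x[obs]; yi <- y[obs]
  gaps <- which(is.na(out))
  if (!length(gaps)) return(out)
  out[gaps] <- stineman_eval(xi, yi, x[gaps])
  out
}

# Stineman slope estimates: tangent of the circle through three consecutive
# knots at the middle knot; secant slope where the points are collinear.
stineman_slopes <- function(x, y) {
  n <- length(x)
  s <- diff(y) / diff(x)
  yp <- numeric(n)
  if (n == 2) return(rep(s, 2))
  for (i in 2:(n - 1)) {
    x1 <- x[i - 1]; y1 <- y[i - 1]
    x2 <- x[i]; y2 <- y[i]
    x3 <- x[i + 1]; y3 <- y[i + 1]
    d <- 2 * ((x1 - x3) * (y2 - y3) - (x2 - x3) * (y1 - y3))
    if (abs(d) < 1e-12 * (abs(x3 - x1) + abs(y3 - y1))^2 || d == 0) {
      yp[i] <- (s[i - 1] + s[i]) / 2  # collinear: secant slope
      next
    }
    a1 <- x1^2 - x3^2 + y1^2 - y3^2
    a2 <- x2^2 - x3^2 + y2^2 - y3^2
    cx <- (a1 * (y2 - y3) - a2 * (y1 - y3)) / d
    cy <- (a2 * (x1 - x3) - a1 * (x2 - x3)) / d
    yp[i] <- if (abs(y2 - cy) < 1e-12) sign(s[i - 1] + s[i]) * 1e6
      else -(x2 - cx) / (y2 - cy)
  }
  # local extrema get slope 0 (shape preservation)
  for (i in 2:(n - 1)) if (s[i - 1] * s[i] <= 0) yp[i] <- 0
  # end slopes by reflection, clamped to the secant's sign and magnitude range
  clamp_end <- function(raw, sec) {
    if (sec == 0) return(0)
    if (sign(raw) != sign(sec)) return(sec)
    sign(sec) * min(abs(raw), 3 * abs(sec))
  }
  yp[1] <- clamp_end(2 * s[1] - yp[2], s[1])
  yp[n] <- clamp_end(2 * s[n - 1] - yp[n - 1], s[n - 1])
  yp
}

# Evaluate the Stineman rational interpolant at points xout within the knots.
stineman_eval <- function(x, y, xout) {
  yp <- stineman_slopes(x, y)
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx >= length(x)] <- length(x) - 1
  s <- diff(y) / diff(x)
  vapply(seq_along(xout), function(k) {
    i <- idx[k]; xx <- xout[k]
    yo <- y[i] + s[i] * (xx - x[i])
    dy1 <- (y[i] + yp[i] * (xx - x[i])) - yo
    dy2 <- (y[i + 1] + yp[i + 1] * (xx - x[i + 1])) - yo
    pr <- dy1 * dy2
    if (pr > 0) {
      yo + pr / (dy1 + dy2)
    } else if (pr < 0) {
      yo + pr * (2 * xx - x[i] - x[i + 1]) /
        ((dy1 - dy2) * (x[i + 1] - x[i]))
    } else yo
  }, numeric(1))
}
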