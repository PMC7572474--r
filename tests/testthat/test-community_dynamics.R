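test_that("relative abundance normalizes columns to unit sums", {
  X <- rbind(A = c(3, 1), B = c(1, 3))
  colnames(X) <- c("t1", "t2")
  ra <- relative_abundance(X)
  expect_equal(ra["A", "t1"], 0.75)
  expect_equal(colSums(ra), c(t1 = 1, t2 = 1))
  expect_equal(unname(relative_abundance(X[1, , drop = FALSE])[1, ]),
               c(1, 1))
  X[, 2] <- 0
  expect_error(relative_abundance(X), "t2")
})

test_that("correlation distance has the documented endpoints", {
  t <- 1:10
  P <- rbind(a = t, b = 2 * t + 3, c = -t, d = sin(t) * 0 + 9)
  expect_warning(D <- correlation_distance_matrix(P), "constant")
  expect_equal(D["a", "b"], 0)          # rho = 1
  expect_equal(D["a", "c"], 1)          # rho = -1
  expect_true(is.na(D["a", "d"]))       # undefined correlation
  set.seed(1)
  P2 <- rbind(x = rnorm(200), y = rnorm(200))
  D2 <- correlation_distance_matrix(P2)
  expect_equal(D2["x", "y"], 0.5, tolerance = 0.15)  # rho ~ 0
  expect_true(all(D2 >= 0 & D2 <= 1))
})

test_that("PERMANOVA partition matches the brute-force oracle exactly", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(2 * n), n)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("p", 1:n), paste0("p", 1:n))
    g <- sample(rep(c("u", "v"), c(floor(n / 2), ceiling(n / 2))))
    res <- permanova(D, g, n_perm = 9, seed = 1)
    want <- oracle_permanova_partition(D, g)
    expect_equal(res$R2, want$R2)
    expect_equal(res$SS_total, want$ss_total)
    expect_equal(res$SS_within, want$ss_within)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on R2 and F", {
  set.seed(4)
  X <- matrix(rnorm(30), 15)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:15), paste0("p", 1:15))
  g <- rep(c("u", "v", "w"), 5)
  res <- permanova(D, g, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 99)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA p matches exhaustive label enumeration on 6 points", {
  set.seed(9)
  X <- matrix(rnorm(12), 6)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:6), paste0("p", 1:6))
  g <- c("a", "a", "a", "b", "b", "b")
  obs <- permanova(D, g, n_perm = 10000, seed = 5)
  # all 20 assignments of 3 labels "a" out of 6
  combs <- utils::combn(6, 3)
  Fs <- apply(combs, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    part <- oracle_permanova_partition(D, gg)
    ssb <- part$ss_total - part$ss_within
    (ssb / 1) / (part$ss_within / 4)
  })
  exact_p <- mean(Fs >= Fs[1] - 1e-12)  # column 1 is the observed labelling
  expect_equal(obs$p, exact_p, tolerance = 0.02)
})

test_that("degenerate group inputs are rejected", {
  D <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  expect_error(permanova(D, rep("a", 4), n_perm = 9), "two groups")
  expect_error(permanova(D, c("a", "a", "a", "b"), n_perm = 9),
               "two members")
})

test_that("duplicated group points give R2 = 1 and infinite F", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  res <- permanova(D, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(res$R2, 1)
  expect_true(is.infinite(res$pseudo_F))
  expect_lt(res$p, 0.5)
})

test_that("dispersion test sees equal spread as null, unequal as signal", {
  set.seed(12)
  # mirror-image groups: same spread
  X <- rbind(cbind(rnorm(15, -3, 1), rnorm(15)),
             cbind(rnorm(15, 3, 1), rnorm(15)))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:30), paste0("p", 1:30))
  g <- rep(c("l", "r"), each = 15)
  res <- dispersion_test(D, g, n_perm = 199, seed = 1)
  expect_gt(res$p, 0.05)
  # one tight, one dispersed group
  small_ps <- replicate(10, {
    Y <- rbind(cbind(rnorm(15, -3, .1), rnorm(15, 0, .1)),
               cbind(rnorm(15, 3, 2), rnorm(15, 0, 2)))
    DY <- as.matrix(dist(Y))
    dimnames(DY) <- list(paste0("p", 1:30), paste0("p", 1:30))
    dispersion_test(DY, g, n_perm = 99, seed = 1)$p
  })
  expect_gt(mean(small_ps < 0.05), 0.8)
})

test_that("dispersion distances agree with vegan::betadisper centroids", {
  set.seed(13)
  X <- matrix(rnorm(40), 20)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:20), paste0("p", 1:20))
  g <- rep(c("u", "v"), each = 10)
  res <- dispersion_test(D, g, n_perm = 9, seed = 1)
  ref <- vegan::betadisper(as.dist(D), g, type = "centroid")
  expect_equal(unname(res$distances), unname(ref$distances),
               tolerance = 1e-8)
})

test_that("temporal stability is mean over sample s.d.", {
  P <- rbind(a = c(2, 4), b = c(3, 3))
  colnames(P) <- c("t1", "t2")
  st <- temporal_stability(P)
  expect_equal(st$stability[1], 3 / sqrt(2))
  expect_true(st$undefined[2])
  expect_true(is.na(st$stability[2]))
})

test_that("excluding the disturbance window raises stability of spiked rMAGs", {
  ok <- logical(5)
  for (s in 1:5) {
    sim <- cached_sim(s, small = FALSE)
    ra <- relative_abundance(sim$truth$abundance)
    st_in <- temporal_stability(ra)
    st_ex <- temporal_stability(ra, sim$truth$disturbance_window)
    i <- match(sim$truth$disturbance_rmags, st_in$rmag_id)
    ok[s] <- mean(st_ex$stability[i] > st_in$stability[i]) >= 0.9
  }
  expect_gte(sum(ok), 4L)
})

test_that("Bray-Curtis matches formula oracle and vegan, with PCoA", {
  set.seed(21)
  X <- matrix(rexp(60), 10)
  colnames(X) <- paste0("s", 1:6)
  res <- braycurtis_pcoa(X)
  expect_equal(unname(res$D), unname(oracle_braycurtis(X)))
  ref <- as.matrix(vegan::vegdist(t(X), method = "bray"))
  expect_equal(unname(res$D), unname(ref), tolerance = 1e-10)
  expect_true(all(res$D >= 0 & res$D <= 1))
  # identical samples at distance 0, disjoint supports at 1
  Y <- cbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(0, 2))
  resY <- suppressWarnings(braycurtis_pcoa(Y))
  expect_equal(resY$D["s1", "s2"], 0)
  expect_equal(resY$D["s1", "s3"], 1)
  Y[, 1] <- 0
  expect_error(braycurtis_pcoa(Y), "all-zero")
})

test_that("vector fitting returns axis-aligned arrows with R2 scaling", {
  set.seed(30)
  emb <- cbind(rnorm(20), rnorm(20))
  rownames(emb) <- paste0("s", 1:20)
  ab <- data.frame(f_axis1 = emb[, 1],
                   f_noise = rnorm(20),
                   f_const = rep(1, 20))
  rownames(ab) <- rownames(emb)
  expect_warning(res <- fit_factors(emb, ab, n_perm = 99, seed = 1),
                 "f_const")
  a1 <- res[res$factor == "f_axis1", ]
  expect_equal(a1$R2, 1, tolerance = 1e-8)
  expect_equal(abs(a1$arrow1), 1, tolerance = 1e-6)
  expect_equal(a1$arrow2, 0, tolerance = 1e-6)
  expect_lt(res$R2[res$factor == "f_noise"], 0.35)
  # arrow norm equals sqrt(R2) for every fitted factor
  norms <- sqrt(res$arrow1^2 + res$arrow2^2)
  expect_equal(norms, sqrt(pmax(0, res$R2)), tolerance = 1e-8)
})

test_that("vector fitting agrees with vegan::envfit R2", {
  set.seed(31)
  emb <- cbind(rnorm(25), rnorm(25))
  rownames(emb) <- paste0("s", 1:25)
  ab <- data.frame(fa = emb[, 1] + rnorm(25, 0, 0.7),
                   fb = rnorm(25))
  rownames(ab) <- rownames(emb)
  res <- fit_factors(emb, ab, n_perm = 99, seed = 1)
  ref <- vegan::envfit(emb, scale(ab), permutations = 99)
  expect_equal(res$R2, unname(ref$vectors$r), tolerance = 1e-8)
})

test_that("Spearman associations match rank-then-Pearson with ties", {
  set.seed(33)
  ab <- matrix(rnorm(40), 8, dimnames = list(paste0("t", 1:8),
                                             c("f1", "f2", "f3", "f4", "f5")))
  X <- matrix(sample(1:4, 24, replace = TRUE), 3,
              dimnames = list(c("a", "b", "c"), paste0("t", 1:8)))
  res <- spearman_associations(X, ab)
  for (k in seq_len(nrow(res))) {
    want <- oracle_spearman(X[res$rmag_id[k], ], ab[, res$factor[k]])
    expect_equal(res$rho[k], want, tolerance = 1e-10)
  }
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))
  # monotone pairs at the extremes
  X2 <- rbind(up = 1:8, down = 8:1)
  colnames(X2) <- paste0("t", 1:8)
  res2 <- spearman_associations(X2, ab[, 1, drop = FALSE], min_pairs = 5)
  expect_true(all(abs(res2$rho) <= 1))
  g <- cbind(g = 1:8)
  rownames(g) <- paste0("t", 1:8)
  res3 <- spearman_associations(X2, g, min_pairs = 5)
  expect_equal(res3$rho[res3$rmag_id == "up"], 1)
  expect_equal(res3$rho[res3$rmag_id == "down"], -1)
})

test_that("z-scores center and scale, preserving missing values", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(c(1, NA, 3))
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_warning(zc <- zscore(c(2, 2, 2)), "constant")
  expect_equal(zc, c(0, 0, 0))
})

test_that("Stineman imputation is exact on linear segments and monotone", {
  y <- c(1, NA, 3)
  expect_equal(stineman_impute(y), c(1, 2, 3))
  y2 <- c(5, 4, 3, 2)
  expect_identical(stineman_impute(y2), y2)  # no gaps: identity
  expect_warning(out <- stineman_impute(c(NA, 2, 3, NA)), "gaps")
  expect_equal(out, c(2, 2, 3, 3))
  set.seed(40)
  for (i in 1:100) {
    n <- sample(6:15, 1)
    y <- sort(rnorm(n)) * sample(c(-1, 1), 1)
    gaps <- sample(2:(n - 1), sample(1:3, 1))
    yg <- y; yg[gaps] <- NA
    filled <- stineman_impute(yg)
    for (g in gaps) {
      lo <- max(which(!is.na(yg[1:(g - 1)])))
      hi <- g + min(which(!is.na(yg[(g + 1):n])))
      expect_true(filled[g] >= min(yg[lo], yg[hi]) - 1e-12 &&
                    filled[g] <= max(yg[lo], yg[hi]) + 1e-12)
    }
  }
})
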