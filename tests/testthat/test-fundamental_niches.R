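test_that("KO presence matrix marks any-gene presence, sorted columns", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    rmag_id = c("A", "A", "A", "B", "B"),
    ko_id = c("K2", "K1", "K1", "K3", NA),
    foam_l1 = NA_character_, length_bp = 100L)
  M <- build_ko_presence(ann, c("A", "B"))
  expect_equal(colnames(M), c("K1", "K2", "K3"))
  expect_equal(M["A", ], c(K1 = 1L, K2 = 1L, K3 = 0L))
  expect_equal(M["B", ], c(K1 = 0L, K2 = 0L, K3 = 1L))
  expect_error(build_ko_presence(ann[0, ], "A"), "empty")
})

test_that("Jaccard distances follow the set formula with safe 0/0", {
  M <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))
  D <- jaccard_distances(M)
  expect_equal(D["a", "b"], 0.5)  # 1 - 2/4
  M2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(0, 0), d = c(0, 0))
  expect_warning(D2 <- jaccard_distances(M2), "all-zero")
  expect_equal(D2["a", "b"], 0)
  expect_equal(D2["c", "d"], 0)
  expect_equal(D2["a", "c"], 1)
})

test_that("Jaccard distances match brute-force sets on random matrices", {
  set.seed(7)
  for (i in 1:100) {
    M <- random_binary_matrix(sample(3:8, 1), sample(4:15, 1),
                              p = runif(1, 0.2, 0.8))
    expect_equal(suppressWarnings(jaccard_distances(M)),
                 oracle_jaccard(M))
  }
})

test_that("classical MDS recovers planted planar configurations", {
  set.seed(1)
  X <- cbind(rnorm(15), rnorm(15))
  rownames(X) <- paste0("p", 1:15)
  D <- as.matrix(dist(X))
  emb <- classical_mds(D, 2)
  expect_lt(procrustes_protest(X, emb, n_perm = 9, seed = 1)$m2, 1e-10)
  ve <- attr(emb, "variance_explained")
  expect_equal(sum(ve), 1, tolerance = 1e-8)
  # collinear points keep their spacing along the first axis
  Dc <- as.matrix(dist(c(0, 1, 2)))
  rownames(Dc) <- colnames(Dc) <- c("x", "y", "z")
  embc <- suppressWarnings(classical_mds(Dc, 2))
  expect_equal(abs(diff(embc[, 1])), c(1, 1), ignore_attr = TRUE)
  # two points at distance 1 map to +-0.5
  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("u", "v"), c("u", "v")))
  emb2 <- suppressWarnings(classical_mds(D2, 2))
  expect_equal(sort(emb2[, 1]), c(-0.5, 0.5), ignore_attr = TRUE)
})

test_that("MDS embedding is row-order invariant", {
  set.seed(2)
  M <- random_binary_matrix(10, 30)
  D <- jaccard_distances(M)
  e1 <- classical_mds(D)
  perm <- sample(nrow(D))
  e2 <- classical_mds(D[perm, perm])
  expect_lt(procrustes_protest(e1, e2[rownames(e1), ],
                               n_perm = 9, seed = 1)$m2, 1e-10)
})

test_that("kneedle elbow picks the point farthest from the chord", {
  expect_equal(nichescope:::kneedle_k(1:9, c(100, 20, 18, 17, 16, 15, 14,
                                             13, 12)), 2L)
  expect_warning(k0 <- nichescope:::kneedle_k(1:9, rep(0, 9)), "elbow")
  expect_equal(k0, 1L)
  expect_warning(k1 <- nichescope:::kneedle_k(1:4, c(1, 2, 3, 4)), "elbow")
  expect_equal(k1, 1L)
})

test_that("identical points give zero within-SS and k = 1", {
  X <- matrix(1, 8, 2)
  expect_warning(res <- choose_k_elbow(X, 1:5, seed = 1), "elbow")
  expect_equal(res$k, 1L)
})

test_that("k-means assignment separates planted groups, labels by size", {
  X <- rbind(matrix(rnorm(20, 0, .05), 10), matrix(rnorm(8, 5, .05), 4))
  rownames(X) <- paste0("r", 1:14)
  out <- kmeans_assign(X, 2, seed = 3)
  expect_equal(unname(out$cluster[1:10]), rep(1L, 10))  # larger group = 1
  expect_equal(unname(out$cluster[11:14]), rep(2L, 4))
  expect_equal(unname(kmeans_assign(X, 1, seed = 1)$cluster),
               rep(1L, 14))
  kn <- kmeans_assign(X, nrow(X), seed = 1)
  expect_equal(kn$tot_withinss, 0)
  expect_error(kmeans_assign(X, 15, seed = 1), "exceeds")
})

test_that("KO set overlaps partition the global union", {
  M <- rbind(A1 = c(1, 1, 1, 0), A2 = c(1, 1, 1, 0), B1 = c(0, 1, 1, 1),
             B2 = c(0, 1, 1, 1))
  colnames(M) <- paste0("K", 1:4)
  cl <- c(A1 = 1L, A2 = 1L, B1 = 2L, B2 = 2L)
  ovl <- ko_set_overlaps(M, cl)
  expect_equal(unname(ovl$union_sizes), c(3L, 3L))
  reg <- stats::setNames(ovl$regions$count, ovl$regions$subset)
  expect_equal(reg[["1"]], 1L)
  expect_equal(reg[["2"]], 1L)
  expect_equal(reg[["1&2"]], 2L)
  # single cluster: one region equal to the union
  ovl1 <- ko_set_overlaps(M, stats::setNames(rep(1L, 4), rownames(M)))
  expect_equal(ovl1$regions$count, 4L)
})

test_that("overlap regions match brute-force set arithmetic", {
  set.seed(11)
  for (i in 1:30) {
    M <- random_binary_matrix(8, 20)
    cl <- stats::setNames(sample(1:3, 8, replace = TRUE), rownames(M))
    while (length(unique(cl)) < 2)
      cl <- stats::setNames(sample(1:3, 8, replace = TRUE), rownames(M))
    ovl <- ko_set_overlaps(M, cl)
    sets <- lapply(sort(unique(cl)), function(g)
      colnames(M)[colSums(M[names(cl)[cl == g], , drop = FALSE]) > 0])
    names(sets) <- sort(unique(cl))
    want <- oracle_overlap_partition(sets)
    got <- stats::setNames(ovl$regions$count, ovl$regions$subset)
    expect_equal(sort(unlist(got)), sort(unlist(as.list(want))),
                 ignore_attr = TRUE)
    expect_equal(sum(ovl$regions$count),
                 length(unique(unlist(sets))))
  }
})

test_that("Fisher enrichment matches the exact hypergeometric tail", {
  # KO present in all 10 members of a 10-cluster and nowhere else
  M <- matrix(0L, 40, 1, dimnames = list(paste0("r", 1:40), "K1"))
  M[1:10, 1] <- 1L
  cl <- stats::setNames(rep(c(1L, 2L), c(10, 30)), rownames(M))
  res <- fisher_enrichment(M, cl)
  p_want <- 1 / choose(40, 10)
  expect_equal(res$p[res$cluster == 1], p_want)
  # agrees with fisher.test one-sided
  ft <- stats::fisher.test(matrix(c(10, 0, 0, 30), 2),
                           alternative = "greater")
  expect_equal(res$p[res$cluster == 1], ft$p.value)
  # ubiquitous KO is never enriched
  M2 <- matrix(1L, 40, 1, dimnames = list(paste0("r", 1:40), "K1"))
  res2 <- fisher_enrichment(M2, cl)
  expect_true(all(res2$p == 1))
})

test_that("BH adjustment follows the step-up procedure", {
  M <- random_binary_matrix(12, 25)
  cl <- stats::setNames(rep(1:2, each = 6), rownames(M))
  res <- fisher_enrichment(M, cl)
  expect_equal(res$p_adj, oracle_bh(res$p))
  expect_equal(stats::p.adjust(c(.01, .02, .03, .04), "BH"),
               rep(0.04, 4))
  expect_true(all(res$p_adj >= res$p))
})

test_that("completeness-adjusted prevalence divides by mean completeness", {
  M <- matrix(0L, 24, 2, dimnames = list(paste0("r", 1:24), c("K1", "K2")))
  M[1:12, "K1"] <- 1L
  cl <- stats::setNames(rep(1L, 24), rownames(M))
  cl[1] <- 1L
  q <- data.frame(mag_id = rownames(M), completeness = 0.762)
  ap <- adjusted_prevalence(M, cl, q, "K1")
  expect_equal(unname(ap), 0.5 / 0.762)
  # full prevalence at completeness 1 gives exactly 1; zero stays zero
  q2 <- data.frame(mag_id = rownames(M), completeness = 1)
  expect_equal(unname(adjusted_prevalence(M, cl, q2,
                                          c("K1", "K2"))[1]) <= 1, TRUE)
  expect_equal(unname(adjusted_prevalence(M, cl, q2, "K2")), 0)
  M[] <- 1L
  expect_equal(unname(adjusted_prevalence(M, cl, q2, "K1")), 1)
})

test_that("Procrustes m2 is zero for rotated scaled copies; p is bounded", {
  set.seed(5)
  X <- cbind(rnorm(20), rnorm(20))
  rownames(X) <- paste0("p", 1:20)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- 3.2 * X %*% R + 5
  rownames(Y) <- rownames(X)
  res <- procrustes_protest(X, Y, n_perm = 99, seed = 2)
  expect_lt(res$m2, 1e-10)
  expect_equal(res$correlation, 1, tolerance = 1e-6)
  expect_equal(res$p, 1 / 100)  # permutation lower bound
})

test_that("Procrustes statistics agree with vegan's protest", {
  set.seed(6)
  X <- cbind(rnorm(15), rnorm(15)); rownames(X) <- paste0("p", 1:15)
  Y <- X + matrix(rnorm(30, 0, 0.6), 15); rownames(Y) <- rownames(X)
  ours <- procrustes_protest(X, Y, n_perm = 199, seed = 3)
  ref <- vegan::protest(X, Y, permutations = 999)
  expect_equal(ours$m2, ref$ss, tolerance = 1e-10)
  expect_equal(ours$correlation, ref$t0, tolerance = 1e-10)
})

test_that("uncorrelated embeddings give low correlation, calibrated p", {
  set.seed(8)
  cors <- ps <- numeric(20)
  for (i in 1:20) {
    X <- cbind(rnorm(25), rnorm(25)); rownames(X) <- paste0("p", 1:25)
    Y <- cbind(rnorm(25), rnorm(25)); rownames(Y) <- rownames(X)
    r <- procrustes_protest(X, Y, n_perm = 99, seed = i)
    cors[i] <- r$correlation; ps[i] <- r$p
  }
  expect_lt(mean(cors), 0.5)
  expect_gt(mean(ps > 0.05), 0.5)  # mostly non-significant under the null
})

test_that("planted functional types are recovered from repertoires", {
  hits <- 0L
  for (s in 1:5) {
    sim <- cached_sim(s, small = FALSE)
    rmags <- rownames(sim$ko_presence)
    D <- jaccard_distances(sim$ko_presence)
    emb <- classical_mds(D, 2)
    ke <- choose_k_elbow(emb, seed = s)
    asg <- kmeans_assign(emb, ke$k, seed = s)
    ari <- adjusted_rand(asg$cluster, sim$truth$type_of_rmag[rmags])
    hits <- hits + (ke$k == 4L && ari >= 0.9)
  }
  expect_gte(hits, 4L)
})
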