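test_that("the gene expression predicate follows its truth table", {
  # (MG >= 1 & MT/MG > 1) | (MG < 1 & MT > 1) | (MP >= 2)
  cases <- rbind(
    c(mg = 2.0, mt = 3.0, mp = 0, want = TRUE),   # ratio 1.5
    c(mg = 2.0, mt = 2.0, mp = 0, want = FALSE),  # ratio exactly 1
    c(mg = 0.5, mt = 1.5, mp = 0, want = TRUE),   # fallback, MT > 1
    c(mg = 0.5, mt = 1.0, mp = 0, want = FALSE),  # fallback, MT exactly 1
    c(mg = 4.0, mt = 1.0, mp = 2, want = TRUE),   # spectral-count rule
    c(mg = 4.0, mt = 1.0, mp = 1, want = FALSE),  # one count is not enough
    c(mg = 0.0, mt = 0.0, mp = 0, want = FALSE),  # nothing measured
    c(mg = 0.0, mt = 1.1, mp = 0, want = TRUE))   # MG 0 takes the fallback
  got <- nichescope:::gene_expressed(cases[, "mg"], cases[, "mt"],
                                     cases[, "mp"])
  expect_equal(got, as.logical(cases[, "want"]), ignore_attr = TRUE)
})

test_that("KO activity is the any-gene aggregate over annotated genes", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    rmag_id = c("A", "A", "A", "B"),
                    ko_id = c("K1", "K1", "K2", "K1"),
                    foam_l1 = NA_character_, length_bp = 100L)
  mg <- c(g1 = 2, g2 = 2, g3 = 2, g4 = 2)
  mt <- c(g1 = 1, g2 = 3, g3 = 1, g4 = 1)
  act <- ko_activity_call(mg, mt, numeric(0), ann)
  key <- paste(act$rmag_id, act$ko_id)
  expect_true(act$active[key == "A K1"])    # g2 carries it
  expect_false(act$active[key == "A K2"])
  expect_false(act$active[key == "B K1"])
  # a gene absent from every table counts as depth zero
  keep <- c("g1", "g2", "g4")
  expect_message(act2 <- ko_activity_call(mg[keep], mt[keep], numeric(0),
                                          ann), "missing")
  key2 <- paste(act2$rmag_id, act2$ko_id)
  expect_true(act2$active[key2 == "A K1"])
  expect_false(act2$active[key2 == "A K2"])
})

test_that("expression clustering finds planted blocks and handles edges", {
  # two blocks of 10 rMAGs with disjoint active KO sets
  A <- matrix(0L, 20, 40,
              dimnames = list(paste0("r", 1:20), paste0("K", 1:40)))
  A[1:10, 1:18] <- 1L
  A[11:20, 21:38] <- 1L
  cl <- cluster_expression_profiles(A)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(length(unique(cl$cluster[1:10])), 1L)
  expect_equal(length(unique(cl$cluster[11:20])), 1L)
  expect_true(all(cl$cluster != 0L))
  # fewer rMAGs than the minimum cluster size: all noise
  cl4 <- cluster_expression_profiles(A[1:4, ])
  expect_equal(unname(cl4$cluster), rep(0L, 4))
  # identical profiles: one cluster containing everyone
  A2 <- matrix(1L, 10, 5, dimnames = list(paste0("r", 1:10), paste0("K", 1:5)))
  cl2 <- cluster_expression_profiles(A2)
  expect_equal(cl2$n_clusters, 1L)
  expect_equal(unname(cl2$cluster), rep(1L, 10))
})

test_that("expression clustering is invariant to rMAG input order", {
  set.seed(55)
  A <- rbind(matrix(rbinom(10 * 30, 1, 0.9), 10, 30),
             matrix(rbinom(10 * 30, 1, 0.05), 10, 30))
  A <- cbind(A, rbind(matrix(rbinom(10 * 30, 1, 0.05), 10, 30),
                      matrix(rbinom(10 * 30, 1, 0.9), 10, 30)))
  rownames(A) <- paste0("r", 1:20)
  colnames(A) <- paste0("K", 1:60)
  cl1 <- cluster_expression_profiles(A)
  perm <- sample(20)
  cl2 <- cluster_expression_profiles(A[perm, ])
  expect_equal(adjusted_rand(cl1$cluster[rownames(A)],
                             cl2$cluster[rownames(A)]), 1)
})

test_that("MT/MG ratios summarise per condition and drop undefined", {
  mg <- rbind(A = c(2, 2, 0), B = c(1, 1, 1))
  mt <- rbind(A = c(5, 5, 3), B = c(1, 1, 1))
  colnames(mg) <- colnames(mt) <- c("s1", "s2", "s3")
  cond <- c(s1 = "c1", s2 = "c1", s3 = "c2")
  grp <- c(A = "g1", B = "g1")
  expect_message(res <- mtmg_ratio(mg, mt, grp, cond), "undefined")
  pr <- res$per_rmag
  expect_equal(pr$mean_ratio[pr$rmag_id == "A" & pr$condition == "c1"], 2.5)
  expect_equal(pr$mean_ratio[pr$rmag_id == "B" & pr$condition == "c1"], 1)
  expect_equal(pr$n_samples[pr$rmag_id == "A" & pr$condition == "c2"], 0)
  expect_true(all(c("median", "q25", "q75") %in% names(res$per_group)))
})

test_that("per-type mean MT/MG ratios recover the planted activity level", {
  for (s in 1:3) {
    sim <- cached_sim(s, small = FALSE)
    rmag_mg <- rmag_depth_from_genes(sim$gene_mg, sim$annotations)
    rmag_mt <- rmag_depth_from_genes(sim$gene_mt, sim$annotations)
    cond <- stats::setNames(sim$manifest$condition, sim$manifest$sample_id)
    res <- mtmg_ratio(rmag_mg, rmag_mt, sim$truth$type_of_rmag, cond)
    pr <- res$per_rmag[res$per_rmag$condition == "in_situ", ]
    types <- sim$truth$type_of_rmag[pr$rmag_id]
    for (t in 1:4) {
      meas <- pr$mean_ratio[types == t]
      want <- sim$truth$expected_ratio_type[[t]]
      se <- stats::sd(meas) / sqrt(length(meas))
      expect_lt(abs(mean(meas) - want), 3 * se + 0.02)
    }
  }
})

test_that("co-clustered KO frequency counts clustered time-points only", {
  A_on <- matrix(1L, 6, 2, dimnames = list(paste0("r", 1:6), c("K1", "K2")))
  A_off <- A_on; A_off[, "K1"] <- 0L
  clusters <- list(t1 = stats::setNames(c(1L, 1L, 1L, 1L, 1L, 0L),
                                        paste0("r", 1:6)),
                   t2 = stats::setNames(c(0L, 1L, 1L, 1L, 1L, 1L),
                                        paste0("r", 1:6)),
                   t3 = stats::setNames(c(1L, 1L, 1L, 1L, 1L, 1L),
                                        paste0("r", 1:6)))
  activities <- list(t1 = A_on, t2 = A_on, t3 = A_off)
  res <- cluster_ko_frequency(clusters, activities, "r1", "K1")
  expect_equal(res$count, 1L)  # active at t1/t2 but clustered only at t1/t3
  expect_equal(res$companions$n_cocluster[res$companions$rmag_id == "r2"],
               2L)
  # never-clustered focal rMAG warns and returns zero
  noise <- list(t1 = stats::setNames(rep(0L, 6), paste0("r", 1:6)))
  expect_warning(z <- cluster_ko_frequency(noise, activities["t1"],
                                           "r1", "K1"), "noise")
  expect_equal(z$count, 0L)
  # always active and always clustered counts every time-point
  res2 <- cluster_ko_frequency(clusters[3], activities[3], "r1", "K2")
  expect_equal(res2$count, 1L)
})

test_that("planted activity regimes are recovered at several time-points", {
  sim <- cached_sim(1, small = FALSE)
  aris <- vapply(c("S11", "S31", "S46"), function(tp) {
    act <- suppressMessages(ko_activity_call(
      sim$gene_mg[, tp], sim$gene_mt[, tp], sim$mp_counts[, tp],
      sim$annotations))
    cl <- cluster_expression_profiles(activity_matrix(act))
    adjusted_rand(cl$cluster, sim$truth$type_of_rmag[names(cl$cluster)])
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})
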