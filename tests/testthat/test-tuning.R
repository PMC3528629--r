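test_that("leave-one-out subsets each omit exactly one compound", {
  ids <- sprintf("C%02d", 1:37)
  subs <- loo_subsets(ids)
  expect_length(subs, 37)
  expect_true(all(lengths(subs) == 36))
  omitted <- vapply(subs, function(s) setdiff(ids, s), character(1))
  expect_equal(omitted, ids)  # pairwise distinct, in id order
  expect_error(loo_subsets(ids[1:2]), "at least 3")
})

test_that("disagreement is the permutation-matched mismatch count", {
  ids <- paste0("c", 1:4)
  expect_equal(disagreement(cluster_assignment(ids, c(1, 1, 2, 2)),
                            cluster_assignment(ids, c(1, 1, 2, 2))), 0)
  expect_equal(disagreement(cluster_assignment(ids, c(1, 1, 2, 2)),
                            cluster_assignment(ids, c(2, 2, 1, 1))), 0)
  expect_equal(disagreement(cluster_assignment(ids, c(1, 1, 2, 2)),
                            cluster_assignment(ids, c(1, 2, 1, 2))), 2)
  expect_error(
    disagreement(cluster_assignment(ids, c(1, 1, 2, 2), k = 2),
                 cluster_assignment(ids, c(1, 2, 3, 1), k = 3)),
    "different k"
  )
})

test_that("disagreement matches exhaustive permutation enumeration", {
  withr::with_seed(55, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      n <- sample(6:12, 1)
      la <- sample(k, n, replace = TRUE)
      lb <- sample(k, n, replace = TRUE)
      ids <- paste0("c", seq_len(n))
      got <- disagreement(cluster_assignment(ids, la, k = k),
                          cluster_assignment(ids, lb, k = k))
      expect_identical(got, brute_disagreement(la, lb, k))
    }
  })
})

test_that("disagreement restricts to the common compound set", {
  a <- cluster_assignment(c("c1", "c2", "c3", "c4"), c(1, 1, 2, 2))
  b <- cluster_assignment(c("c2", "c3", "c4", "c5"), c(1, 2, 2, 1))
  expect_equal(disagreement(a, b), 0)
})

test_that("AMD is zero for identical partitions and order-invariant", {
  views <- block_views(n = 8)
  trees <- lapply(loo_subsets(rownames(views[[1]]$S)), function(keep) {
    hierarchical_cluster(to_distance(views[[1]]$S[keep, keep]))
  })
  expect_equal(amd(trees, k_range = c(2, 2)), 0)
  # noisy trees: value unchanged under subset reordering
  trees2 <- lapply(1:5, function(s) {
    hierarchical_cluster(to_distance(rand_similarity(7, seed = s)))
  })
  expect_equal(amd(trees2, k_range = c(2, 4)),
               amd(rev(trees2), k_range = c(2, 4)))
  expect_error(amd(trees2, k_range = c(2, 8)), "exceeds")
})

test_that("Dunn's index follows its definition and the brute-force oracle", {
  # two tight, far-apart pairs
  d <- matrix(1, 4, 4, dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  asg <- cluster_assignment(paste0("c", 1:4), c(1, 1, 2, 2))
  expect_equal(dunn_index(d, asg), 10)
  # consistent relabeling leaves the index unchanged
  asg2 <- cluster_assignment(paste0("c", 1:4), c(2, 2, 1, 1))
  expect_equal(dunn_index(d, asg2), 10)
  expect_error(dunn_index(d, cluster_assignment(paste0("c", 1:4), rep(1, 4))),
               "at least 2")
  withr::with_seed(66, {
    for (i in 1:10) {
      n <- 6
      dd <- to_distance(rand_similarity(n, seed = i + 200))
      labels <- sample(3, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      got <- suppressWarnings(
        dunn_index(dd, cluster_assignment(rownames(dd), labels))
      )
      expect_lt(abs(got - brute_dunn(dd, labels)), 1e-12)
    }
  })
})

test_that("eta tuning reports stability per eta and recommends reproducibly", {
  sc <- planted_scenario(n = 10, k_true = 2, view_noise = c(0, 0),
                         profile_dim = 12, fp_bits = 32, seed = 3)
  views <- generate_views(sc)
  cfg <- fusion_config(eta = 1, seed = 3, n_restarts = 1, max_em = 300)
  rep1 <- tune_eta(views, eta_grid = c(0.1, 10), k_range = c(2, 3),
                   config = cfg)
  expect_s3_class(rep1, "stability_report")
  expect_equal(nrow(rep1$report), 2)
  # unambiguous planted structure is stable for every eta at the planted k
  rep_k2 <- tune_eta(views, eta_grid = c(0.1, 10), k_range = c(2, 2),
                     config = cfg)
  expect_true(all(rep_k2$report$amd == 0))
  # determinism of the recommendation
  rep2 <- tune_eta(views, eta_grid = c(0.1, 10), k_range = c(2, 3),
                   config = cfg)
  expect_identical(tidy(rep1), tidy(rep2))
  expect_identical(rep1$recommendation, rep2$recommendation)
  # degenerate grid
  rep3 <- tune_eta(views, eta_grid = 5, k_range = c(2, 2), config = cfg)
  expect_equal(nrow(rep3$report), 1)
  expect_equal(rep3$recommendation, 5)
})
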