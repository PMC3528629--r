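test_that("cross-entropy evaluates exactly and obeys Gibbs' inequality", {
  P <- matrix(0.25, 2, 2)
  expect_equal(cross_entropy(P, P), log(4))
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  for (s in 1:20) {
    P <- rand_stochastic(4, seed = s)
    Q <- rand_stochastic(4, seed = s + 100)
    expect_gte(cross_entropy(P, Q), cross_entropy(P, P) - 1e-12)
  }
  expect_error(cross_entropy(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("weight entropy handles the simplex boundary", {
  expect_equal(weight_entropy(c(0.5, 0.5)), log(2))
  expect_equal(weight_entropy(c(1, 0)), 0)
  expect_equal(weight_entropy(c(0.25, 0.75)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)))
  expect_error(weight_entropy(c(0.7, 0.7)), "summing to 1")
})

test_that("factorization attains the entropy bound on factorable input", {
  # exactly rank-1: outer product of a stochastic vector with itself
  p <- rand_stochastic(6, 1, seed = 4)[, 1]
  p <- p / sum(p)
  P1 <- outer(p, p)
  m <- fit_factorization(P1, k = 1, seed = 3)
  expect_lt(m$objective - cross_entropy(P1, P1), 1e-6)
  # full-rank k = n can approach equality too
  M <- rand_stochastic(6, seed = 5)
  m2 <- fit_factorization(M, k = 6, seed = 3, max_em = 5000, tol = 1e-12)
  expect_lt(m2$objective - cross_entropy(M, M), 1e-4)
})

test_that("factorization objective is monotone non-increasing", {
  for (s in 1:5) {
    P <- rand_stochastic(8, seed = s)
    m <- fit_factorization(P, k = 3, seed = s)
    expect_true(all(diff(m$trace) <= 1e-9))
    expect_lt(abs(sum(m$Q) - 1), 1e-9)
    expect_gte(min(m$V), 0)
    expect_gte(min(m$H), 0)
  }
})

test_that("factorization validates its inputs", {
  P <- rand_stochastic(4, seed = 1)
  expect_error(fit_factorization(P, k = 5, seed = 1), "exceeds")
  expect_error(fit_factorization(P * 2, k = 2, seed = 1), "sum to 1")
})

test_that("closed-form weights match the simplex grid-search oracle", {
  expect_equal(unname(optimize_weights(c(2.2, 2.2), eta = 0.7)$alpha),
               c(0.5, 0.5))
  w <- optimize_weights(c(1, 2), eta = 1)$alpha
  expect_equal(unname(w), c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)),
               tolerance = 1e-12)
  expect_lt(max(abs(optimize_weights(c(1, 2), eta = 1000)$alpha - 0.5)), 1e-3)
  withr::with_seed(77, {
    for (i in 1:50) {
      ce <- runif(2, 0, 5)
      eta <- exp(runif(1, log(0.05), log(50)))
      a <- optimize_weights(ce, eta)$alpha
      b <- brute_weights_2(ce, eta)
      expect_lt(max(abs(a - b)), 1e-3)
    }
  })
  expect_error(optimize_weights(c(1, 2), eta = 0), "positive")
})

test_that("fusing identical views returns the input similarity and equal weights", {
  views <- block_views()
  res <- fuse(views, fusion_config(eta = 0.5, seed = 1, n_restarts = 2))
  expect_equal(res$fused_S, views[[1]]$S)
  expect_equal(unname(res$alpha), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("fusion favors a structured view over uniform noise", {
  wins <- 0
  for (s in 1:20) {
    sc <- planted_scenario(n = 24, k_true = 4, view_noise = c(0.2, 1),
                           profile_dim = 30, fp_bits = 128, seed = s)
    res <- fuse(generate_views(sc), fusion_config(eta = 3, seed = s,
                                                  n_restarts = 2))
    if (res$alpha[["bioactivity"]] > res$alpha[["structure"]]) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("fusion result satisfies its structural invariants", {
  sc <- planted_scenario(n = 16, k_true = 3, profile_dim = 20, fp_bits = 64,
                         seed = 5)
  views <- generate_views(sc)
  res <- fuse(views, fusion_config(eta = 3, seed = 5, n_restarts = 2))
  # fused_S is the convex combination of the original matrices
  manual <- res$alpha[["bioactivity"]] * views$bioactivity$S +
    res$alpha[["structure"]] * views$structure$S
  expect_lt(max(abs(res$fused_S - manual)), 1e-12)
  expect_lt(max(abs(res$fused_S - t(res$fused_S))), 1e-12)
  expect_equal(sum(res$alpha), 1, tolerance = 1e-12)
  # outer objective non-increasing per restart
  for (tr in split(res$trace$objective, res$trace$restart)) {
    expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("fusion is bit-reproducible and accepts more than two views", {
  sc <- planted_scenario(n = 12, k_true = 3, profile_dim = 15, fp_bits = 32,
                         seed = 9)
  views <- generate_views(sc)
  cfg <- fusion_config(eta = 2, seed = 9, n_restarts = 2)
  expect_identical(fuse(views, cfg), fuse(views, cfg))
  three <- c(views, list(extra = similarity_view("extra", views$bioactivity$S)))
  res3 <- fuse(three, cfg)
  expect_length(res3$alpha, 3)
  expect_equal(sum(res3$alpha), 1, tolerance = 1e-12)
})

test_that("fusion rejects mismatched compound sets", {
  v1 <- block_views()[[1]]
  S <- v1$S
  rownames(S) <- colnames(S) <- paste0("x", seq_len(nrow(S)))
  v2 <- similarity_view("other", S)
  expect_error(fuse(list(v1, v2), fusion_config(eta = 1)), "x1")
})
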