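test_that("scenario validation enforces its invariants", {
  expect_error(planted_scenario(n = 3, k_true = 4), "n >= k_true")
  expect_error(planted_scenario(view_noise = c(0.2, 1.2)), "\\[0, 1\\]")
  expect_error(planted_scenario(profile_dim = 2), "profile_dim")
  expect_error(planted_scenario(fp_bits = 4), "fp_bits")
  sc <- planted_scenario(n = 10, k_true = 3)
  expect_equal(sort(unique(sc$labels$cluster)), 1:3)
  expect_length(sc$compound_ids, 10)
})

test_that("noiseless profiles give within-cluster Pearson similarity 1", {
  sc <- planted_scenario(n = 12, k_true = 3, view_noise = c(0, 0),
                         profile_dim = 15, fp_bits = 32, seed = 2)
  v <- pearson_similarity(generate_profiles(sc))
  for (cl in 1:3) {
    members <- sc$labels$compound_id[sc$labels$cluster == cl]
    expect_equal(unname(v$S[members, members]),
                 matrix(1, length(members), length(members)))
  }
})

test_that("a magnitude offset leaves correlation at 1 but spreads Euclidean distance", {
  sc <- planted_scenario(n = 6, k_true = 3, view_noise = c(0, 0),
                         profile_dim = 20, fp_bits = 32,
                         profile_offset_sd = 10, seed = 4)
  pr <- generate_profiles(sc)
  x <- as.matrix(pr[-1])
  pair <- which(sc$labels$cluster == 1)
  expect_equal(cor(x[pair[1], ], x[pair[2], ]), 1)
  expect_gt(sqrt(sum((x[pair[1], ] - x[pair[2], ])^2)), 5)
})

test_that("noiseless fingerprints are identical within clusters", {
  sc <- planted_scenario(n = 12, k_true = 3, view_noise = c(0, 0),
                         profile_dim = 15, fp_bits = 32, seed = 3)
  v <- tanimoto_similarity(generate_fingerprints(sc))
  for (cl in 1:3) {
    members <- sc$labels$compound_id[sc$labels$cluster == cl]
    expect_equal(unname(v$S[members, members]),
                 matrix(1, length(members), length(members)))
  }
})

test_that("maximal fingerprint noise removes the cluster signal", {
  gaps <- vapply(1:20, function(s) {
    sc <- planted_scenario(n = 16, k_true = 4, view_noise = c(0.2, 1),
                           profile_dim = 15, fp_bits = 256,
                           template_density = 0.5, seed = s)
    S <- tanimoto_similarity(generate_fingerprints(sc))$S
    same <- outer(sc$labels$cluster, sc$labels$cluster, `==`)
    diag(same) <- NA
    off <- upper.tri(S)
    mean(S[off][same[off]]) - mean(S[off][!same[off]])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.02)  # Monte-Carlo error only
})

test_that("every generated fingerprint has at least one set bit", {
  for (s in 1:5) {
    sc <- planted_scenario(n = 10, k_true = 2, view_noise = c(0, 1),
                           profile_dim = 10, fp_bits = 8,
                           template_density = 0.1, seed = s)
    bits <- fingerprint_matrix(generate_fingerprints(sc))
    expect_true(all(rowSums(bits) >= 1))
  }
})

test_that("clean target annotations yield disjoint cluster cliques", {
  sc <- planted_scenario(n = 12, k_true = 3, view_noise = c(0, 0),
                         profile_dim = 15, fp_bits = 32,
                         annotation_noise = 0, seed = 7)
  g <- project_common_target(generate_targets(sc))
  for (cl in 1:3) {
    members <- sc$labels$compound_id[sc$labels$cluster == cl]
    expect_equal(average_degree(g, members), length(members) - 1)
  }
  # no edge crosses clusters
  cl_of <- setNames(sc$labels$cluster, sc$labels$compound_id)
  expect_true(all(cl_of[g$edges$from] == cl_of[g$edges$to]))
})

test_that("full annotation noise creates between-cluster edges", {
  sc <- planted_scenario(n = 20, k_true = 4, view_noise = c(0, 0),
                         profile_dim = 15, fp_bits = 32,
                         annotation_noise = 1, seed = 8)
  g <- project_common_target(generate_targets(sc))
  cl_of <- setNames(sc$labels$cluster, sc$labels$compound_id)
  expect_gt(sum(cl_of[g$edges$from] != cl_of[g$edges$to]), 0)
})

test_that("generators are bit-identical under a fixed seed", {
  sc <- planted_scenario(n = 10, k_true = 2, profile_dim = 10, fp_bits = 16,
                         seed = 99)
  expect_identical(generate_profiles(sc), generate_profiles(sc))
  expect_identical(generate_fingerprints(sc), generate_fingerprints(sc))
  expect_identical(generate_targets(sc)$edges, generate_targets(sc)$edges)
})
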