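# small hand-built scoring fixture: one module {i, j} with controllable
# similarity and distance
pair_fixture <- function(s_terms_i, s_terms_j, d) {
  go <- go_annotations(list(i = s_terms_i, j = s_terms_j))
  D <- matrix(c(0, d, d, 0), 2, 2, dimnames = list(c("i", "j"), c("i", "j")))
  list(ms = module_set(list(c("i", "j"))), go = go, dist = D)
}

test_that("cohesion combines mean intra similarity with inverse mean distance", {
  # s = 0.5 (2 shared of 4 total terms), d = 0.25 -> 0.5 + 1/0.25 = 4.5
  fx <- pair_fixture(c("a", "b"), c("a", "b", "c", "d"), 0.25)
  expect_equal(cohesion(fx$ms, fx$go, fx$dist), 4.5)

  # D = 0: cohesion falls back to S alone
  fx0 <- pair_fixture(c("a", "b"), c("a", "b", "c", "d"), 0)
  expect_equal(cohesion(fx0$ms, fx0$go, fx0$dist), 0.5)

  # all-singleton module set has no intra pair
  D <- fx$dist
  expect_identical(cohesion(module_set(list("i", "j")), fx$go, D), 0)
  expect_error(cohesion(module_set(list()), fx$go, D), "no modules")
})

test_that("separation combines mean cross distance with inverse mean similarity", {
  # two singleton modules: d = 0.9, s = 0.1 -> 0.9 + 10
  go <- go_annotations(list(i = letters[1:1], j = letters[1:10]))  # s = 1/10
  D <- matrix(c(0, 0.9, 0.9, 0), 2, 2,
              dimnames = list(c("i", "j"), c("i", "j")))
  ms <- module_set(list("i", "j"))
  expect_equal(separation(ms, go, D), 0.9 + 10)

  # S = 0 across modules: separation falls back to D alone
  go0 <- go_annotations(list(i = "a", j = "b"))
  expect_equal(separation(ms, go0, D), 0.9)

  expect_error(separation(module_set(list(c("i", "j"))), go, D),
               "two modules")
})

test_that("evaluation result is internally consistent", {
  inst <- two_triangle_instance()
  D <- cd_distance_matrix(inst$graph)
  # add a weakly shared term so the cross-module similarity is nonzero
  # and both indices take their generic branch
  go <- go_annotations(lapply(unclass(inst$go), function(v) c(v, "GO:0")))
  ms <- module_set(list(c("A1", "A2", "A3"), c("B1", "B2", "B3")))
  ev <- evaluate_modules(ms, go, D)
  expect_equal(ev$cohesion,
               ev$intra_similarity + 1 / ev$intra_distance)
  expect_equal(ev$separation,
               ev$inter_distance + 1 / ev$inter_similarity)
  expect_equal(ev$cohesion, cohesion(ms, go, D))
  expect_equal(ev$separation, separation(ms, go, D))
  expect_identical(ev$n_modules, 2L)
})

test_that("cohesion and separation respond monotonically to their inputs", {
  fx <- pair_fixture(c("a", "b"), c("a", "c"), 0.5)    # s = 1/3
  base <- cohesion(fx$ms, fx$go, fx$dist)
  # raise the intra similarity, all else fixed
  go_hi <- go_annotations(list(i = c("a", "b"), j = c("a", "b")))
  expect_gt(cohesion(fx$ms, go_hi, fx$dist), base)

  ms2 <- module_set(list("i", "j"))
  sep_base <- separation(ms2, fx$go, fx$dist)
  D_far <- fx$dist; D_far["i", "j"] <- D_far["j", "i"] <- 0.9
  expect_gt(separation(ms2, fx$go, D_far), sep_base)
})

test_that("the planted partition outscores random partitions of the same shape", {
  inst <- two_triangle_instance()
  D <- cd_distance_matrix(inst$graph)
  # the invariant needs intra d < inter d and intra s > inter s > 0: a
  # weak term shared by every protein keeps cross similarity positive
  # (at exactly 0 the separation index jumps to its degenerate branch)
  go <- go_annotations(lapply(unclass(inst$go), function(v) c(v, "GO:0")))
  truth_ms <- module_set(list(c("A1", "A2", "A3"), c("B1", "B2", "B3")))
  co_true <- cohesion(truth_ms, go, D)
  se_true <- separation(truth_ms, go, D)
  prots <- names(inst$truth)
  set.seed(51)
  for (rep in 1:100) {
    perm <- sample(prots)
    ms <- module_set(list(perm[1:3], perm[4:6]))
    expect_gte(co_true, cohesion(ms, go, D) - 1e-12)
    expect_gte(se_true, separation(ms, go, D) - 1e-12)
  }
})

test_that("adjusted Rand index handles identity, label permutation and mismatch", {
  ms <- module_set(list(c("A", "B"), c("C", "D", "E")))
  truth <- c(A = "x", B = "x", C = "y", D = "y", E = "y")
  expect_equal(adjusted_rand_index(ms, truth), 1)

  # permuting truth label names leaves the ARI unchanged
  truth2 <- c(A = "q", B = "q", C = "p", D = "p", E = "p")
  expect_equal(adjusted_rand_index(ms, truth2), 1)

  # one giant predicted cluster against a k > 1 truth
  giant <- module_set(list(c("A", "B", "C", "D", "E")))
  expect_lte(adjusted_rand_index(giant, truth), 0)

  # unassigned proteins form their own cluster
  ms_un <- module_set(list(c("A", "B")), unassigned = c("C", "D", "E"))
  expect_equal(adjusted_rand_index(ms_un, truth), 1)

  expect_error(adjusted_rand_index(ms, truth[-1]), "different proteins")
})
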