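test_that("tour segmentation cuts at steps above the threshold", {
  D <- cd_distance_matrix(fig_ppin())
  tour <- nn_initial_tour(D)  # A, D, E, C, B, F
  ms <- segment_tour(tour, D, 0.40)
  expect_identical(ms$modules, list(c("A", "D"), c("B", "C", "E", "F")))
  expect_identical(ms$unassigned, character(0))

  expect_identical(segment_tour(tour, D, 1)$modules,
                   list(sort(tour$order)))
  all_single <- segment_tour(tour, D, 0)$modules
  expect_identical(lengths(all_single), rep(1L, 6))
})

test_that("segment count is monotonically non-increasing in the threshold", {
  set.seed(41)
  D <- random_symmetric_dist(20)
  tour <- nn_initial_tour(D)
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(d) length(segment_tour(tour, D, d)$modules),
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("protein similarity follows the Jaccard rule with conventions", {
  expect_identical(protein_similarity(c("t1"), c("t9"), same_protein = TRUE), 1)
  expect_equal(protein_similarity(c("t1", "t2"), c("t2", "t3")), 1/3)
  expect_identical(protein_similarity(c("t1"), c("t2")), 0)
  expect_identical(protein_similarity(character(0), character(0)), 0)
})

test_that("module similarity sums cross pairs over the smaller module size", {
  go <- go_annotations(list(
    i1 = c("a", "b", "c", "d", "e"),      # s(i1, j1) = 1/5  -> not 0.2? use exact sets
    i2 = c("a", "b"),
    j1 = c("a", "b", "c", "d", "e")))
  # s(i1, j1) = 1, s(i2, j1) = 2/5
  expect_equal(module_similarity(c("i1", "i2"), "j1", go), 1 + 2/5)
  # singletons: S equals s
  expect_equal(module_similarity("i2", "j1", go), 2/5)
  # disjoint annotations everywhere
  go2 <- go_annotations(list(x = "t1", y = "t2"))
  expect_identical(module_similarity("x", "y", go2), 0)
  # symmetry and overlap error
  expect_equal(module_similarity("j1", c("i1", "i2"), go),
               module_similarity(c("i1", "i2"), "j1", go))
  expect_error(module_similarity(c("i1", "j1"), c("j1"), go), "overlap")
})

test_that("functional merging is a fixed point below the threshold and merges above it", {
  go <- go_annotations(list(
    a1 = c("t1", "t2"), a2 = c("t1", "t2"),
    b1 = c("t1", "t3"),
    c1 = c("t9")))
  ms <- module_set(list(c("a1", "a2"), "b1", "c1"))
  # S({a1,a2},{b1}) = 2*(1/3) = 2/3 > 0.5 -> merge; c1 shares nothing
  merged <- merge_by_function(ms, go, 0.5)
  expect_identical(merged$modules, list(c("a1", "a2", "b1"), "c1"))

  unchanged <- merge_by_function(ms, go, 10)
  expect_identical(unchanged$modules, ms$modules)
})

test_that("a merge can raise a third module above the threshold (cascade)", {
  # A and B share term p; the singleton C overlaps each of them only a
  # little, but once A and B merge the cross-pair sum against C clears
  # the threshold (the min-size denominator stays 1).
  go <- go_annotations(list(
    a1 = c("p", "q"), a2 = c("p", "q"),
    b1 = c("p", "r"), b2 = c("p", "r"),
    c1 = c("q", "r", "y", "z", "w")))
  ms <- module_set(list(c("a1", "a2"), c("b1", "b2"), "c1"))
  theta <- 0.5
  expect_gt(module_similarity(c("a1", "a2"), c("b1", "b2"), go), theta)
  expect_lte(module_similarity(c("a1", "a2"), "c1", go), theta)
  expect_lte(module_similarity(c("b1", "b2"), "c1", go), theta)
  # exhaustive recomputation of the post-merge pair confirms the cascade
  expect_gt(module_similarity(c("a1", "a2", "b1", "b2"), "c1", go), theta)
  merged <- merge_by_function(ms, go, theta)
  expect_identical(merged$modules, list(c("a1", "a2", "b1", "b2", "c1")))
})

test_that("merging conserves the partition and terminates within the merge bound", {
  set.seed(42)
  inst <- generate_ppin(synth_spec(module_sizes = c(6L, 6L, 6L), seed = 5))
  D <- cd_distance_matrix(inst$graph)
  tour <- nn_initial_tour(D)
  pre <- segment_tour(tour, D, 0.5)
  merged <- merge_by_function(pre, inst$go, 0.3)
  expect_identical(module_set_proteins(merged), module_set_proteins(pre))
  expect_lte(length(merged$modules), length(pre$modules))
  expect_gte(length(merged$modules), 1L)
})

test_that("module density counts internal interactions over possible pairs", {
  g <- fig_ppin()
  expect_identical(module_density(c("B", "D", "E"), g), 1)   # triangle
  expect_equal(module_density(c("A", "B", "D"), g), 2/3)     # A-B, B-D
  expect_equal(module_density(c("A", "B", "E", "F"), g), 3/6)  # A-B, B-E, E-F
  expect_identical(module_density("A", g), 0)                # singleton
})

test_that("density filtering moves whole low-density modules to unassigned", {
  g <- ppin(c("B", "B", "D", "A", "X"), c("D", "E", "E", "B", "E"),
            quiet = TRUE)
  ms <- module_set(list(c("B", "D", "E"), c("A", "X")))
  filtered <- filter_by_density(ms, g, density_min = 0.5)
  expect_identical(filtered$modules, list(c("B", "D", "E")))
  expect_identical(filtered$unassigned, c("A", "X"))

  # density_min 0 keeps every non-singleton module
  expect_identical(filter_by_density(ms, g, 0)$modules, ms$modules)
  # density_min 1 keeps only cliques
  only_cliques <- filter_by_density(ms, g, 1)
  expect_identical(only_cliques$modules, list(c("B", "D", "E")))
  # singletons kept only on request
  ms2 <- module_set(list("A", c("B", "D", "E")))
  expect_identical(length(filter_by_density(ms2, g, 0)$modules), 1L)
  expect_identical(length(filter_by_density(ms2, g, 0,
                                            keep_singletons = TRUE)$modules),
                   2L)
})

test_that("module_set enforces disjointness and nonemptiness", {
  expect_error(module_set(list(c("A", "B"), c("B", "C"))), "disjoint")
  expect_error(module_set(list(character(0))), "empty")
  expect_error(module_set(list("A"), unassigned = "A"), "overlap")
})
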