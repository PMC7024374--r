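# Pairing enumeration, distance-matrix scoring, connectivity comparison.

test_that("pairing enumeration yields the double factorial, uniquely", {
  expect_length(enumerate_pairings(2), 1L)
  p6 <- enumerate_pairings(6)
  expect_length(p6, 15L)
  expect_length(enumerate_pairings(8), 105L)
  labels <- vapply(p6, pairing_label, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  expect_error(enumerate_pairings(5), "even")
})

test_that("pairing labels are canonical", {
  expect_equal(pairing_label(rbind(c(4, 3), c(6, 1), c(2, 5))),
               "C1-C6/C2-C5/C3-C4")
})

test_that("the SG-SG matrix averages the lowest-energy models", {
  ref <- reference_structure(tg[["B"]], helix_b, conn_165234, seed = 21)
  rt <- simulate_restraints(ref)
  cfg <- anneal_config(n_steps = 150, seed = 55)
  e <- generate_ensemble(tg[["B"]], rt, n = 4, config = cfg)

  m1 <- ss_distance_matrix(e, k = 1)
  best <- select_lowest(e, 1)$models[[1]]
  sg <- e$layout$particle[e$layout$is_sg]
  expect_equal(unname(m1$mean_dist), unname(as.matrix(dist(best[sg, ]))),
               tolerance = 1e-12)
  expect_equal(m1$cys_positions, c(7L, 11L, 16L, 24L, 27L, 31L))

  # brute-force average over the k = 3 lowest
  m3 <- ss_distance_matrix(e, k = 3)
  low <- select_lowest(e, 3)
  acc <- Reduce(`+`, lapply(low$models, function(x) as.matrix(dist(x[sg, ])))) / 3
  expect_equal(unname(m3$mean_dist), unname(acc), tolerance = 1e-12)

  # duplicated models leave the mean unchanged
  e2 <- e
  e2$models <- c(e$models[1], e$models[1])
  e2$energies <- c(1, 1)
  e2$seeds <- c(1L, 2L)
  e1 <- e2
  e1$models <- e1$models[1]
  e1$energies <- 1
  e1$seeds <- 1L
  expect_equal(ss_distance_matrix(e2, k = 2)$mean_dist,
               ss_distance_matrix(e1, k = 1)$mean_dist)
  expect_error(ss_distance_matrix(e, k = 10), "fewer")
})

test_that("score_pairings finds the exhaustive minimum matching", {
  # a 2-cysteine matrix has a single trivial pattern
  m2 <- matrix(c(0, 4.2, 4.2, 0), 2, 2)
  sc2 <- score_pairings(m2)
  expect_equal(nrow(sc2), 1L)
  expect_equal(sc2$label, "C1-C2")
  expect_equal(sc2$score, 4.2)

  set.seed(101)
  for (i in 1:200) {
    a <- matrix(runif(36, 2, 20), 6, 6)
    dm <- (a + t(a)) / 2
    diag(dm) <- 0
    sc <- score_pairings(dm)
    oracle <- oracle_best_matching(dm)
    expect_equal(sc$label[1], oracle$label)
    expect_equal(sc$score[1], oracle$score, tolerance = 1e-9)
    expect_equal(attr(sc, "margin"), sc$score[2] - sc$score[1])
    expect_false(is.unsorted(sc$score))
  }
})

test_that("scores are equivariant under cysteine relabeling", {
  set.seed(103)
  a <- matrix(runif(36, 2, 20), 6, 6)
  dm <- (a + t(a)) / 2
  diag(dm) <- 0
  sc <- score_pairings(dm)
  perm <- sample(6)
  dmp <- dm[perm, perm]
  scp <- score_pairings(dmp)
  # scores are the same multiset; the top score is identical
  expect_equal(sort(scp$score), sort(sc$score), tolerance = 1e-9)
  # the winning pairs map through the permutation: relabel and compare
  top <- attr(sc, "pairs")[[1]]
  inv <- order(perm)
  mapped <- matrix(inv[top], ncol = 2)
  expect_equal(scp$label[1], pairing_label(mapped))
})

test_that("constrained re-refinement summaries are deterministic", {
  ref <- reference_structure(tg[["B"]], helix_b, conn_165234, seed = 21)
  rt <- simulate_restraints(ref)
  cfg <- anneal_config(n_steps = 150, seed = 60)
  one <- compare_connectivities(tg[["B"]], rt, list(conn_165234),
                                n = 2, k = 2, config = cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$label, "C1-C6/C2-C5/C3-C4")

  twice <- compare_connectivities(tg[["B"]], rt, list(conn_165234, conn_165234),
                                  n = 2, k = 2, config = cfg)
  expect_equal(twice$mean_lowk[1], twice$mean_lowk[2])
  expect_equal(twice$min_energy[1], twice$min_energy[2])
})
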