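# Distance bounds, embedding, energies, annealing, ensembles, RMSD.

test_that("coarse layout has one CA per residue and SC per non-glycine", {
  lay <- coarse_layout("GAGC")
  expect_equal(sum(lay$type == "CA"), 4L)
  expect_equal(sum(lay$type == "SC"), 2L)
  expect_equal(lay$res[lay$is_sg], 4L)
  bonds <- attr(lay, "bonds")
  expect_equal(nrow(bonds), 3L + 2L)
  expect_true(all(bonds$target[1:3] == 3.8))
  sg_bond <- bonds[bonds$j == lay$particle[lay$is_sg], ]
  expect_equal(sg_bond$target, 2.8)
})

test_that("bounds matrices respect bonds, restraints, and triangle smoothing", {
  b <- bounds_matrix("GGG")
  lay <- b$layout
  ca <- lay$particle[lay$type == "CA"]
  # two-bond path limits the 1-3 distance
  expect_lte(b$upper[ca[1], ca[3]], 2 * 3.9)
  expect_equal(b$upper[ca[1], ca[2]], 3.9)
  expect_equal(b$lower[ca[1], ca[2]], 3.7)

  geo <- data.frame(p_i = 1, p_j = 5, lower = 1.8, upper = 3.5)
  b2 <- bounds_matrix("GGGGG", geo)
  expect_lte(b2$upper[1, 5], 3.5)

  # an over-tight bound on a bonded pair is clamped: covalent geometry wins
  geo_bond <- data.frame(p_i = 1, p_j = 2, lower = 1.8, upper = 3.5)
  b3 <- bounds_matrix("GGGGG", geo_bond)
  expect_equal(b3$upper[1, 2], b3$lower[1, 2])

  # a restraint below the contact floor on a non-bonded pair is inconsistent
  geo_bad <- data.frame(p_i = 1, p_j = 5, lower = 1.8, upper = 1.0)
  expect_error(bounds_matrix("GGGGG", geo_bad), "inconsistent")
})

test_that("embedding reproduces exact distances and is seed-deterministic", {
  set.seed(3)
  x <- matrix(rnorm(15, sd = 4), 5, 3)
  d <- as.matrix(dist(x))
  bounds <- list(lower = d, upper = d)
  y <- dg_embed(bounds, seed = 1, refine_iters = 0)
  expect_equal(as.matrix(dist(y)), d, tolerance = 1e-6, ignore_attr = TRUE)

  b <- bounds_matrix("GGGGGGGG")
  e1 <- dg_embed(b, seed = 5)
  e2 <- dg_embed(b, seed = 5)
  expect_identical(e1, e2)
  expect_false(isTRUE(all.equal(e1, dg_embed(b, seed = 6))))
})

test_that("embedding a clean synthetic bound set satisfies most restraints", {
  ref <- reference_structure(tg[["B"]], helix_b, conn_165234, seed = 21)
  rt <- simulate_restraints(ref)
  geo <- to_geometric(rt, tg[["B"]])
  b <- bounds_matrix(tg[["B"]], geo)
  sat <- vapply(1:5, function(s) restraint_satisfaction(dg_embed(b, s), geo),
                numeric(1))
  expect_gte(mean(sat), 0.5)
})

test_that("the energy function is a non-negative sum of violation terms", {
  # two glycines at the bond target, no restraints: zero energy
  x <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  expect_equal(model_energy(x, "GG"), 0)

  # one restrained pair exactly 1 A above its upper bound, unit weight
  cfg <- anneal_config(weights = c(noe = 1, chain = 0, rep = 0, ss = 0))
  geo <- data.frame(p_i = 1, p_j = 2, lower = 1.8, upper = 2.8)
  expect_equal(model_energy(x, "GG", geo, config = cfg), 1.0)

  set.seed(23)
  for (i in 1:10) {
    n <- 8
    x <- matrix(rnorm(2 * n * 3, sd = 3), 2 * n, 3)
    seqs <- random_sequence(n)
    lay <- coarse_layout(seqs)
    x <- x[seq_len(nrow(lay)), , drop = FALSE]
    expect_gte(model_energy(x, seqs), 0)
  }
})

test_that("annealing is seeded, monotone at the optimum, and reproducible", {
  x0 <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  cfg <- anneal_config(n_steps = 200, seed = 9)
  fit <- anneal_model(x0, "GG", config = cfg)
  expect_equal(fit$energy, 0)  # an optimal start cannot get worse

  ref <- reference_structure(tg[["B"]], helix_b, conn_165234, seed = 21)
  rt <- simulate_restraints(ref)
  geo <- to_geometric(rt, tg[["B"]])
  b <- bounds_matrix(tg[["B"]], geo)
  start <- dg_embed(b, seed = 31)
  cfg <- anneal_config(n_steps = 300, seed = 31)
  f1 <- anneal_model(start, tg[["B"]], geo, config = cfg)
  f2 <- anneal_model(start, tg[["B"]], geo, config = cfg)
  expect_identical(f1$coords, f2$coords)
  expect_identical(f1$energy, f2$energy)
  expect_lte(f1$energy, model_energy(start, tg[["B"]], geo, config = cfg) + 1e-9)
})

test_that("ensembles record seeds and select_lowest keeps the energy prefix", {
  ref <- reference_structure(tg[["B"]], helix_b, conn_165234, seed = 21)
  rt <- simulate_restraints(ref)
  cfg <- anneal_config(n_steps = 150, seed = 77)
  e <- generate_ensemble(tg[["B"]], rt, n = 8, config = cfg)
  expect_length(e$models, 8L)
  expect_equal(e$seeds, 77L + 0:7)

  e_rep <- generate_ensemble(tg[["B"]], rt, n = 8, config = cfg)
  expect_identical(e$models, e_rep$models)
  expect_identical(e$energies, e_rep$energies)

  low <- select_lowest(e, 3)
  expect_equal(low$energies, sort(low$energies))
  expect_lte(max(low$energies), min(setdiff(e$energies, low$energies)))
  all8 <- select_lowest(e, 8)
  expect_setequal(all8$energies, e$energies)
  expect_error(select_lowest(e, 0), "1..8")
  expect_error(select_lowest(e, 9), "fewer|1..8")
})

test_that("backbone RMSD is a superposition-invariant pseudo-metric", {
  lay <- coarse_layout("GGGGGGGGGG")
  set.seed(41)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(backbone_rmsd(a, a, lay), 0)

  # arbitrary rigid motion leaves the RMSD at zero
  th <- 0.8
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- a %*% rot + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  expect_lt(backbone_rmsd(a, b, lay), 1e-6)

  # displacing one particle by d among N gives at most d/sqrt(N)
  d <- 2.0
  b2 <- a; b2[4, 1] <- b2[4, 1] + d
  r <- backbone_rmsd(a, b2, lay)
  expect_lte(r, d / sqrt(10) + 1e-9)
  expect_gt(r, 0.5 * d / sqrt(10))

  # cross-check against an independent superposition implementation
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b2)),
                                         fixed.inds = 1:30, mobile.inds = 1:30))
  r_bio3d <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(r, r_bio3d, tolerance = 1e-6)

  # pseudo-metric: symmetry and triangle inequality on random triples
  for (i in 1:5) {
    x <- matrix(rnorm(30, sd = 4), 10, 3)
    y <- matrix(rnorm(30, sd = 4), 10, 3)
    z <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(backbone_rmsd(x, y, lay), backbone_rmsd(y, x, lay), tolerance = 1e-9)
    expect_lte(backbone_rmsd(x, z, lay),
               backbone_rmsd(x, y, lay) + backbone_rmsd(y, z, lay) + 1e-9)
  }
})
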