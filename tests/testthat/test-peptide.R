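# Peptide construction, mass arithmetic, isotopes, fragments, charge and pI.

test_that("parse_peptide builds validated peptides from sequence + mod strings", {
  p <- parse_peptide("GIKEM", "Mox@5")
  expect_s3_class(p, "peptide")
  expect_length(p$residues, 5L)
  expect_equal(p$mods, data.frame(name = "mox", pos = 5L))

  p0 <- parse_peptide("G", "")
  expect_length(p0$residues, 1L)
  expect_equal(nrow(p0$mods), 0L)

  p_ss <- parse_peptide("GACGCA", "amide,SS:3-5")
  expect_equal(p_ss$c_term, "amide")
  expect_equal(p_ss$ss_bonds, list(c(3L, 5L)))

  expect_error(parse_peptide("GAXG"), "unknown residue")
  expect_error(parse_peptide("GACG", "SS:2-2"), "distinct")
  expect_error(parse_peptide("GIKEM", "Mox@2"), "requires Met")
  expect_error(parse_peptide("GACGC", "CAM@1"), "requires Cys")
  expect_error(parse_peptide("CACGC", "SS:1-3,3-5"), "reused")
  expect_error(parse_peptide("G", "wobble"), "cannot parse")
})

test_that("monoisotopic mass follows residue + water + modification deltas", {
  expect_equal(monoisotopic_mass(peptide("G")), 75.03203, tolerance = 1e-5)
  d <- modification_deltas()
  expect_equal(unname(d["mox"]), 15.994915, tolerance = 1e-6)
  expect_equal(unname(d["amide"]), -0.984016, tolerance = 1e-6)
  expect_equal(unname(d["ss"]), -2.015650, tolerance = 1e-6)
  expect_equal(unname(d["cam"]), 57.021464, tolerance = 1e-6)
})

test_that("disulfide mass additivity is exact", {
  set.seed(42)
  for (i in 1:25) {
    seqs <- paste0("C", random_sequence(10), "C", random_sequence(5), "CC")
    cys <- which(strsplit(seqs, "")[[1]] == "C")
    reduced <- peptide(seqs)
    for (k in 1:2) {
      bonds <- lapply(seq_len(k), function(j) cys[c(2 * j - 1, 2 * j)])
      oxidized <- peptide(seqs, ss_bonds = bonds)
      expect_identical(monoisotopic_mass(oxidized),
                       monoisotopic_mass(reduced) - k * 2 * 1.00782503207)
    }
  }
})

test_that("elemental composition implies the monoisotopic mass", {
  expect_equal(elemental_composition(peptide("G")),
               c(C = 2, H = 5, N = 1, O = 2))
  expect_equal(elemental_composition(peptide("GG")),
               c(C = 4, H = 8, N = 2, O = 3))

  elmass <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
              O = 15.9949146196, S = 31.97207100)
  pB <- peptide(tg[["B"]], c_term = "amide", ss_bonds = ss_b)
  comp <- elemental_composition(pB)
  expect_lt(abs(sum(elmass[names(comp)] * comp) - monoisotopic_mass(pB)), 1e-6)

  set.seed(7)
  for (i in 1:1000) {
    p <- peptide(random_sequence(sample(3:25, 1)),
                 c_term = sample(c("free", "amide"), 1))
    comp <- elemental_composition(p)
    expect_lt(abs(sum(elmass[names(comp)] * comp) - monoisotopic_mass(p)), 1e-6)
  }
})

test_that("isotope distributions are normalized convolutions of element patterns", {
  c1 <- isotope_distribution(c(C = 1), 2)
  expect_equal(c1$abundances[2] / c1$abundances[1], 0.0107 / 0.9893, tolerance = 1e-9)

  h2o <- isotope_distribution(c(H = 2, O = 1), 5)
  # A+0 is the product of lightest-isotope probabilities
  expect_equal(h2o$abundances[1], (1 - 0.000115)^2 * 0.99757, tolerance = 1e-6)

  empty <- isotope_distribution(c(), 3)
  expect_equal(empty$abundances, 1)

  set.seed(11)
  for (i in 1:50) {
    comp <- c(C = sample(0:80, 1), H = sample(0:120, 1), N = sample(0:20, 1),
              O = sample(0:25, 1), S = sample(0:4, 1))
    ip <- isotope_distribution(comp, 30)
    expect_true(all(ip$abundances >= 0))
    expect_lt(abs(sum(ip$abundances) - 1), 1e-9)
  }
  expect_error(isotope_distribution(c(Xx = 2)), "unknown element")
})

test_that("b/y fragments reproduce reference values and complementarity", {
  b <- fragment_ions(peptide("GIKEM"), "b")
  expect_equal(round(b$mz[b$index == 5], 2), 559.29)

  bm <- fragment_ions(parse_peptide("GIKEM", "Mox@5"), "b")
  expect_equal(bm$mz[bm$index == 5], 559.2908 + 15.994915, tolerance = 2e-3)

  g <- fragment_ions(peptide("G"), "b")
  expect_equal(g$mz[1], 58.029, tolerance = 1e-3)

  expect_error(fragment_ions(peptide("CACC", ss_bonds = list(c(1, 3)))),
               "without disulfide")

  set.seed(13)
  proton <- 1.007276466879
  for (i in 1:50) {
    p <- peptide(random_sequence(sample(4:20, 1)),
                 c_term = sample(c("free", "amide"), 1))
    n <- length(p$residues)
    M <- monoisotopic_mass(p)
    fb <- fragment_ions(p, "b")
    fy <- fragment_ions(p, "y")
    for (idx in seq_len(n - 1)) {
      expect_lt(abs(fb$mz[fb$index == idx] + fy$mz[fy$index == n - idx] -
                      (M + 2 * proton)), 1e-6)
    }
  }
})

test_that("net charge is monotone in pH and hits the textbook limits", {
  expect_equal(net_charge(peptide("K"), 1), 2, tolerance = 0.01)
  expect_equal(net_charge(peptide("D"), 13), -2, tolerance = 0.01)

  set.seed(17)
  for (i in 1:20) {
    p <- peptide(random_sequence(sample(5:30, 1)))
    ph <- sort(runif(12, 0.5, 13.5))
    ch <- vapply(ph, function(x) net_charge(p, x), numeric(1))
    expect_true(all(diff(ch) <= 1e-12))
  }
})

test_that("isoelectric point is the bisection root of the charge curve", {
  # two-group case has the closed-form midpoint of the terminal pKas
  pk <- default_pka()
  expect_equal(isoelectric_point(peptide("GG")),
               (pk[["n_term"]] + pk[["c_term"]]) / 2, tolerance = 1e-3)

  set.seed(19)
  for (i in 1:10) {
    p <- peptide(random_sequence(sample(5:30, 1)))
    expect_lt(abs(net_charge(p, isoelectric_point(p))), 1e-4)
  }
  # amidated oligoglycine has no acidic group left
  expect_error(isoelectric_point(peptide("GGG", c_term = "amide")), "sign change")
})
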