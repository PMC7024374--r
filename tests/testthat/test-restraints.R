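# NOE classes, geometric mapping, couplings, helix propensity, TSV I/O.

test_that("NOE classes map to the canonical distance bounds", {
  expect_equal(classify_noe("strong"), c(lower = 1.8, upper = 2.5))
  expect_equal(classify_noe("medium"), c(lower = 1.8, upper = 3.7))
  expect_equal(classify_noe("weak"), c(lower = 1.8, upper = 5.0))
  expect_error(classify_noe("verystrong"), "unknown NOE class")
})

test_that("restraint tables validate input and count categories stably", {
  df <- data.frame(res_i = c(5, 7, 1, 2), atom_i = c("HN", "SC", "HN", "HA"),
                   res_j = c(6, 24, 30, 3), atom_j = c("HN", "SC", "HN", "HN"),
                   class = c("strong", "weak", "medium", "weak"))
  t <- noe_table(df, 30)
  expect_s3_class(t, "restraint_table")
  expect_equal(t$upper, c(2.5, 5.0, 3.7, 5.0))
  cats <- restraint_categories(t)
  expect_equal(unname(cats["sequential"]), 2L)
  expect_equal(unname(cats["long_range"]), 2L)
  expect_equal(unname(cats["total"]), 4L)
  expect_equal(sum(cats[c("intra", "sequential", "medium_range", "long_range")]),
               unname(cats["total"]))
  # counts are invariant under row permutation
  t2 <- noe_table(df[c(3, 1, 4, 2), ], 30)
  expect_equal(restraint_categories(t2), cats)

  expect_error(noe_table(data.frame(res_i = 1, atom_i = "HN", res_j = 40,
                                    atom_j = "HN", class = "weak"), 30), "outside")
  expect_error(noe_table(data.frame(res_i = 1, atom_i = "HX", res_j = 2,
                                    atom_j = "HN", class = "weak"), 30), "atom tag")
})

test_that("proton restraints map onto coarse particles with corrections", {
  seqs <- "GAAAAACAAAAAAAAAAAAAAAAAAAAAAA"  # G1, C7, rest A; 30 residues
  t <- noe_table(data.frame(res_i = c(5, 7), atom_i = c("HN", "HB"),
                            res_j = c(6, 24), atom_j = c("HN", "HB"),
                            class = c("strong", "weak")), 30)
  geo <- to_geometric(t, seqs)
  lay <- coarse_layout(seqs)
  expect_equal(geo$p_i[1], lay$particle[lay$res == 5 & lay$type == "CA"])
  expect_equal(geo$p_j[1], lay$particle[lay$res == 6 & lay$type == "CA"])
  expect_equal(geo$upper[1], 2.5 + 1.0)
  expect_equal(geo$p_i[2], lay$particle[lay$res == 7 & lay$type == "SC"])
  expect_equal(geo$upper[2], 5.0 + 1.5)

  tg_gly <- noe_table(data.frame(res_i = 1, atom_i = "SC", res_j = 5,
                                 atom_j = "HN", class = "weak"), 30)
  expect_error(to_geometric(tg_gly, seqs), "glycine")
})

test_that("the Karplus curve reproduces the helix and sheet anchors", {
  expect_gte(karplus_j(-60), 3.5)
  expect_lte(karplus_j(-60), 4.5)
  expect_gte(karplus_j(-120), 8.5)
  expect_lte(karplus_j(-120), 9.5)
  expect_equal(karplus_j(-60, A = 0, B = 0, C = 2.2), 2.2)
  expect_error(karplus_j(200), ">= -180")
})

test_that("couplings classify into helix / averaged / sheet bands", {
  expect_equal(as.character(j_classify(c(4, 6.5, 9))),
               c("helix", "averaged", "sheet"))
  expect_equal(as.character(j_classify(c(6.0, 7.5))), c("averaged", "averaged"))
})

test_that("helix propensity flags NN>aN runs supported by i,i+3 contacts", {
  # ideal-helix reference -> zero-noise restraints -> helix segment recovered
  ref <- reference_structure(paste(rep("A", 12), collapse = ""), list(c(1, 12)))
  rt <- simulate_restraints(ref)
  hp <- helix_propensity(rt)
  expect_true(all(hp$score[3:9] >= 1))
  expect_gt(nrow(hp$segments), 0L)
  expect_lte(hp$segments$start[1], 3L)
  expect_gte(hp$segments$end[nrow(hp$segments)], 9L)

  empty <- noe_table(data.frame(res_i = integer(), atom_i = character(),
                                res_j = integer(), atom_j = character(),
                                class = character()), 12)
  hp0 <- helix_propensity(empty)
  expect_equal(hp0$score, rep(0, 12))
  expect_equal(nrow(hp0$segments), 0L)

  lr <- noe_table(data.frame(res_i = c(1, 2), atom_i = "HN",
                             res_j = c(10, 12), atom_j = "HN",
                             class = "weak"), 12)
  expect_equal(helix_propensity(lr)$score, rep(0, 12))
})

test_that("restraint TSV round-trips and rejects malformed rows", {
  t <- noe_table(data.frame(res_i = c(5, 1), atom_i = c("HN", "HA"),
                            res_j = c(6, 4), atom_j = c("HN", "HN"),
                            class = c("strong", "weak")), 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(t, path)
  t2 <- read_restraints(path)
  expect_equal(as.data.frame(t2), as.data.frame(t))
  expect_equal(attr(t2, "sequence_length"), 10L)
  expect_equal(t2$upper[1], 2.5)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# sequence_length=10", "x\tHN\t6\tHN\tstrong"), bad)
  expect_error(read_restraints(bad), "line 1")
})
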