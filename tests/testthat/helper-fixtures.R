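# Shared fixtures and independent oracles.

tg <- turgencin_sequences()

# disulfide topologies on the two sequences (cysteine residue positions)
ss_a <- list(c(8, 26), c(12, 29), c(17, 33))
ss_b <- list(c(7, 31), c(11, 27), c(16, 24))

# C1-C6/C2-C5/C3-C4 as cysteine ordinals
conn_165234 <- rbind(c(1, 6), c(2, 5), c(3, 4))

helix_b <- list(c(6, 14), c(23, 31))

# random peptide sequence under the caller's RNG state
random_sequence <- function(n) {
  paste(sample(amino_acids()$code, n, replace = TRUE), collapse = "")
}

# Independent minimum-matching oracle: builds matchings from permutations
# (a different route than the package's recursive pairing enumeration) and
# returns the minimum total distance and its canonical label.
oracle_best_matching <- function(dm) {
  n <- nrow(dm)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  best_label <- NULL
  for (p in perms(seq_len(n))) {
    pairs <- matrix(p, ncol = 2, byrow = TRUE)
    s <- sum(dm[pairs])
    lab <- pairing_label(pairs)
    if (s < best - 1e-12 || (abs(s - best) <= 1e-12 && lab < best_label)) {
      best <- s
      best_label <- lab
    }
  }
  list(score = best, label = best_label)
}

# brute-force mass of (sequence + C-terminal extension + mods) built as a
# fresh peptide object, for cross-checking explain_delta's delta arithmetic
oracle_candidate_mass <- function(base_seq, extension, amidated, n_mox, n_cam) {
  full <- paste0(base_seq, extension)
  res <- strsplit(full, "")[[1]]
  mets <- which(res == "M")[seq_len(n_mox)]
  cyss <- which(res == "C")[seq_len(n_cam)]
  mods <- data.frame(name = c(rep("mox", n_mox), rep("cam", n_cam)),
                     pos = c(mets, cyss))
  monoisotopic_mass(peptide(full, c_term = if (amidated) "amide" else "free",
                            mods = mods))
}
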