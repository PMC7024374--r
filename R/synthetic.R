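# Synthetic fixtures with known ground truth: coarse helix-loop-helix
# reference structures with a chosen disulfide topology, noisy distance-class
# restraint tables derived from them, and mass observations over random
# modification sets. Everything is deterministic given its seed.

.HELIX_RISE <- 1.5    # A per residue
.HELIX_TWIST <- 100   # degrees per residue
.HELIX_RADIUS <- 2.3  # A

# ideal CA trace: helical inside the spans, extended elsewhere, laid out as
# consecutive segments along z
.reference_trace <- function(n, helix_segments) {
  helical <- logical(n)
  for (sp in helix_segments) {
    if (sp[1] < 1L || sp[2] > n || sp[1] > sp[2]) stop("helix span outside sequence")
    helical[sp[1]:sp[2]] <- TRUE
  }
  coords <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  k <- 0L # index within the current helical run
  for (i in seq_len(n)) {
    if (i == 1L) {
      coords[i, ] <- pos
      k <- if (helical[i]) 1L else 0L
      next
    }
    if (helical[i] && helical[i - 1L]) {
      a0 <- (k - 1L) * .HELIX_TWIST * pi / 180
      a1 <- k * .HELIX_TWIST * pi / 180
      step <- c(.HELIX_RADIUS * (cos(a1) - cos(a0)),
                .HELIX_RADIUS * (sin(a1) - sin(a0)),
                .HELIX_RISE)
      k <- k + 1L
    } else {
      step <- c(0, 0, .BOND_CA_CA)
      k <- if (helical[i]) 1L else 0L
    }
    pos <- pos + step
    coords[i, ] <- pos
  }
  list(coords = coords, helical = helical)
}

# side-chain particles point away from the local backbone
.place_side_chains <- function(ca, lay) {
  n_res <- max(lay$res)
  coords <- matrix(NA_real_, nrow(lay), 3)
  coords[lay$type == "CA", ] <- ca
  for (r in which(tabulate(lay$res, n_res) == 2L)) {
    prev <- ca[max(1L, r - 1L), ]
    nxt <- ca[min(n_res, r + 1L), ]
    dir <- ca[r, ] - (prev + nxt) / 2
    if (sqrt(sum(dir^2)) < 1e-6) dir <- c(1, 0, 0)
    dir <- dir / sqrt(sum(dir^2))
    p <- lay$particle[lay$res == r & lay$type == "SC"]
    len <- if (lay$is_sg[p]) .BOND_CA_SG else .BOND_CA_SC
    coords[p, ] <- ca[r, ] + dir * len
  }
  coords
}

#' Build a reference coarse structure with known disulfide topology
#'
#' Without a connectivity, lays down an ideal CA trace (canonical alpha-helix
#' geometry of 1.5 A rise, 100 degrees per residue, 2.3 A radius inside the
#' helix spans; extended elsewhere) and places side-chain particles outward.
#' With a connectivity, the chain is folded so the bridged SG pairs sit at
#' ~2.05 A: a distance-geometry embed seeded with the SG-SG bounds and
#' helix-preserving i,i+3 bounds is refined by a short seeded annealing run.
#' Fails with an error if any bridged pair cannot be brought below 2.5 A.
#'
#' @param sequence one-letter residue string.
#' @param helix_segments list of residue spans \code{c(from, to)}.
#' @param connectivity optional 2-column matrix of cysteine ordinals (the
#'   generating disulfide pattern).
#' @param seed integer seed.
#' @return object of class \code{coarse_model}: list with \code{coords},
#'   \code{layout}, \code{sequence}, \code{connectivity}.
#' @examples
#' m <- reference_structure("AAAAAAAAAA", list(c(1, 10)))
#' @export
reference_structure <- function(sequence, helix_segments = list(),
                                connectivity = NULL, seed = 1L) {
  lay <- coarse_layout(sequence)
  n_res <- max(lay$res)
  tr <- .reference_trace(n_res, helix_segments)
  coords <- .place_side_chains(tr$coords, lay)

  if (!is.null(connectivity) && NROW(connectivity) > 0L) {
    connectivity <- matrix(as.integer(connectivity), ncol = 2)
    sg <- .sg_particles(lay)
    if (any(connectivity < 1L | connectivity > length(sg))) {
      stop("connectivity pairs must index the sequence's cysteines")
    }
    # helix-preserving i,i+3 bounds around the ideal 5.3 A
    geo <- NULL
    rows <- list()
    ca <- lay$particle[lay$type == "CA"]
    for (sp in helix_segments) {
      if (sp[2] - sp[1] >= 3L) {
        for (i in sp[1]:(sp[2] - 3L)) {
          rows[[length(rows) + 1L]] <- data.frame(p_i = ca[i], p_j = ca[i + 3L],
                                                  lower = 4.8, upper = 5.8)
        }
      }
    }
    if (length(rows)) geo <- do.call(rbind, rows)

    bounds <- bounds_matrix(sequence, geo, ss = connectivity)
    for (attempt in 0:2) {
      s_a <- seed + 7919L * attempt
      start <- dg_embed(bounds, seed = s_a)
      cfg <- anneal_config(t_start = 200, n_steps = 2000L,
                           weights = c(noe = 5, chain = 10, rep = 1, ss = 20),
                           seed = s_a)
      fit <- anneal_model(start, sequence, geo = geo, ss = connectivity, config = cfg)
      # quench: remove residual clashes and bond strain so the reference is
      # a comfortable feasible point for the restraints derived from it
      cfg_q <- anneal_config(t_start = 2, t_end = 0.001, n_steps = 1500L,
                             move_max = 0.1, move_min = 0.01,
                             weights = c(noe = 5, chain = 20, rep = 5, ss = 50),
                             seed = s_a + 1L)
      fit <- anneal_model(fit$coords, sequence, geo = geo, ss = connectivity, config = cfg_q)
      ssp <- .ss_particle_pairs(lay, connectivity)
      dss <- sqrt(rowSums((fit$coords[ssp[, 1], , drop = FALSE] -
                           fit$coords[ssp[, 2], , drop = FALSE])^2))
      if (all(dss < 2.5)) {
        coords <- fit$coords
        break
      }
      if (attempt == 2L) {
        stop("connectivity unsatisfiable: SG-SG distance ",
             sprintf("%.2f", max(dss)), " A after constrained minimization")
      }
    }
  }
  structure(list(coords = coords, layout = lay, sequence = sequence,
                 connectivity = connectivity, helix_segments = helix_segments,
                 seed = seed),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("coarse model: %d residues, %d particles", max(x$layout$res), nrow(x$layout)))
  if (!is.null(x$connectivity)) cat(", connectivity", pairing_label(x$connectivity))
  cat("\n")
  invisible(x)
}

#' Simulate an NOE restraint table from a reference structure
#'
#' Every inter-residue particle pair whose distance, after removing the
#' pseudo-particle correction (+1.0 A backbone, +1.5 A side chain), lies
#' within \code{contact_cutoff} yields a restraint of the tightest class
#' consistent with that corrected distance, so the reference satisfies its
#' own zero-noise table. Each
#' sequential CA-CA contact is emitted as the experimentally distinct pair of
#' HN(i)-HN(i+1) and HA(i)-HN(i+1) cross peaks, classed by local helicity
#' (detected from the CA(i)-CA(i+3) distance), and helical stretches
#' additionally emit the HA(i)-HN(i+3) signature peak. Restraints are then
#' independently dropped with \code{drop_rate} and class-shifted by one level
#' with \code{misclass_rate}.
#'
#' @param model a [reference_structure()] result.
#' @param contact_cutoff contact distance in Angstrom (default 5.0).
#' @param misclass_rate probability of shifting a restraint's class one level.
#' @param drop_rate probability of dropping a restraint.
#' @param seed integer seed for the noise draws.
#' @return a [noe_table()].
#' @export
simulate_restraints <- function(model, contact_cutoff = 5.0,
                                misclass_rate = 0, drop_rate = 0, seed = 1L) {
  stopifnot(inherits(model, "coarse_model"),
            misclass_rate >= 0, misclass_rate <= 1, drop_rate >= 0, drop_rate <= 1)
  lay <- model$layout
  xyz <- model$coords
  n_res <- max(lay$res)
  d <- as.matrix(stats::dist(xyz))
  ca <- lay$particle[lay$type == "CA"]

  helical <- rep(FALSE, n_res)
  for (i in seq_len(max(0L, n_res - 3L))) {
    dd <- d[ca[i], ca[i + 3L]]
    helical[i] <- dd >= 4.0 && dd <= 6.0
  }

  class_for <- function(dd, corr) {
    eff <- dd - corr
    if (eff <= 2.5) "strong" else if (eff <= 3.7) "medium" else "weak"
  }
  rows <- list()
  emit <- function(ri, ai, rj, aj, cls) {
    rows[[length(rows) + 1L]] <<- data.frame(res_i = ri, atom_i = ai,
                                             res_j = rj, atom_j = aj,
                                             class = cls, stringsAsFactors = FALSE)
  }
  np <- nrow(lay)
  for (p in seq_len(np - 1L)) {
    for (q in (p + 1L):np) {
      ri <- lay$res[p]; rj <- lay$res[q]
      if (ri == rj) next                       # intra-residue: bonded, uninformative
      dd <- d[p, q]
      both_ca <- lay$type[p] == "CA" && lay$type[q] == "CA"
      corr <- if (both_ca) 1.0 else 1.5
      if (dd - corr >= contact_cutoff || dd - corr > 5.0 || dd < 1.8) next
      if (both_ca && abs(ri - rj) == 1L) next  # handled as NN/aN pair below
      emit(ri, if (lay$type[p] == "CA") "HN" else "SC",
           rj, if (lay$type[q] == "CA") "HN" else "SC",
           class_for(dd, corr))
    }
  }
  for (i in seq_len(n_res - 1L)) {
    if (helical[min(i, length(helical))]) {
      emit(i, "HN", i + 1L, "HN", "medium")
      emit(i, "HA", i + 1L, "HN", "weak")
    } else {
      emit(i, "HN", i + 1L, "HN", "weak")
      emit(i, "HA", i + 1L, "HN", "medium")
    }
  }
  for (i in seq_len(max(0L, n_res - 3L))) {
    dd <- d[ca[i], ca[i + 3L]]
    if (helical[i] && dd >= 1.8 && dd <= 6.0) emit(i, "HA", i + 3L, "HN", "weak")
  }
  df <- do.call(rbind, rows)

  .with_seed(seed, {
    keep <- stats::runif(nrow(df)) >= drop_rate
    df <- df[keep, , drop = FALSE]
    if (nrow(df)) {
      flip <- stats::runif(nrow(df)) < misclass_rate
      lev <- c("strong", "medium", "weak")
      idx <- match(df$class, lev)
      dir <- ifelse(stats::runif(nrow(df)) < 0.5, -1L, 1L)
      shifted <- pmin(pmax(idx + dir, 1L), 3L)
      df$class[flip] <- lev[shifted[flip]]
    }
  })
  rownames(df) <- NULL
  noe_table(df, n_res)
}

#' Simulate a mass observation with known modification ground truth
#'
#' Treats \code{p} as the true full sequence, samples a modification set --
#' C-terminal truncation of the Edman read (0/1/2 residues with probability
#' 0.5/0.25/0.25), amidation (p = 0.5), Met-ox per methionine (p = 0.3) and
#' carbamidomethyl on one cysteine (p = 0.15) -- computes the true
#' monoisotopic mass of the modified full peptide, and adds a measurement
#' error drawn from a Gaussian of sd \code{ppm_error}/2 truncated at
#' +/- \code{ppm_error} ppm.
#'
#' @param p the true full [peptide()] (free termini, unmodified).
#' @param ppm_error maximum relative error in ppm (default 5).
#' @param menu modification families allowed in the draw.
#' @param seed integer seed.
#' @return list with \code{measured} (Da), \code{read_peptide} (the
#'   truncated peptide the analyst would sequence) and \code{truth} (list
#'   \code{extension}, \code{amidated}, \code{n_met_ox}, \code{n_cam},
#'   \code{true_mass}).
#' @export
simulate_mass <- function(p, ppm_error = 5,
                          menu = c("truncation", "amide", "mox", "cam"),
                          seed = 1L) {
  stopifnot(inherits(p, "peptide"), ppm_error >= 0)
  seqs <- paste(p$residues, collapse = "")
  n <- length(p$residues)
  .with_seed(seed, {
    trunc_len <- if ("truncation" %in% menu) {
      sample(0:2, 1L, prob = c(0.5, 0.25, 0.25))
    } else 0L
    amid <- "amide" %in% menu && stats::runif(1) < 0.5
    n_met <- sum(p$residues == "M")
    n_mox <- if ("mox" %in% menu && n_met) stats::rbinom(1L, n_met, 0.3) else 0L
    n_cys <- sum(p$residues == "C")
    n_cam <- if ("cam" %in% menu && n_cys) stats::rbinom(1L, 1L, 0.15) else 0L

    mets <- which(p$residues == "M")
    cyss <- which(p$residues == "C")
    mox_pos <- if (n_mox) sort(mets[sample.int(length(mets), n_mox)]) else integer()
    cam_pos <- if (n_cam) cyss[sample.int(length(cyss), n_cam)] else integer()
    mods <- data.frame(name = c(rep("mox", n_mox), rep("cam", n_cam)),
                       pos = c(mox_pos, cam_pos))
    true_pep <- peptide(seqs, c_term = if (amid) "amide" else "free", mods = mods)
    true_mass <- monoisotopic_mass(true_pep)

    err_ppm <- 0
    if (ppm_error > 0) {
      repeat {
        err_ppm <- stats::rnorm(1L, 0, ppm_error / 2)
        if (abs(err_ppm) <= ppm_error) break
      }
    }
    measured <- true_mass * (1 + err_ppm * 1e-6)
    read_len <- n - trunc_len
    if (read_len < 1L) stop("truncation removes the whole peptide")
    list(measured = measured,
         read_peptide = peptide(substr(seqs, 1L, read_len)),
         truth = list(extension = substr(seqs, read_len + 1L, n),
                      amidated = amid, n_met_ox = n_mox, n_cam = n_cam,
                      true_mass = true_mass))
  })
}
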