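# Coarse-grained ensemble generation: distance-geometry embedding followed
# by seeded simulated-annealing refinement against NOE-derived bounds.
#
# The model carries one CA particle per residue and one side-chain particle
# (SC) per non-glycine residue; for cysteines the SC particle plays the role
# of the SG sulfur, which is all the disulfide analysis needs.

.BOND_CA_CA <- 3.8
.BOND_CA_SC <- 2.4
.BOND_CA_SG <- 2.8
.SS_TARGET <- 2.05
.REP_DIST <- 3.0

# evaluate expr under a local, seeded RNG without disturbing the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Particle layout of the coarse-grained model
#'
#' @param sequence one-letter residue string.
#' @return data.frame with one row per particle: \code{particle} (index),
#'   \code{res} (residue number), \code{type} (\code{"CA"} or \code{"SC"}),
#'   \code{code} (residue letter) and \code{is_sg} (side-chain particle of a
#'   cysteine). Attribute \code{bonds}: data.frame \code{i}, \code{j},
#'   \code{target} with CA(i)-CA(i+1) at 3.8 A and CA(i)-SC(i) at 2.4 A
#'   (2.8 A for the Cys SG).
#' @export
coarse_layout <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.AA_COMPOSITION))
  if (length(bad)) stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n <- length(res)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(res = i, type = "CA", code = res[i], is_sg = FALSE)
    if (res[i] != "G") {
      rows[[length(rows) + 1L]] <- data.frame(res = i, type = "SC", code = res[i],
                                              is_sg = res[i] == "C")
    }
  }
  lay <- do.call(rbind, rows)
  lay$particle <- seq_len(nrow(lay))
  lay <- lay[, c("particle", "res", "type", "code", "is_sg")]
  ca <- lay$particle[lay$type == "CA"]
  bonds <- data.frame(i = ca[-n], j = ca[-1], target = .BOND_CA_CA)
  sc <- lay[lay$type == "SC", ]
  bonds <- rbind(bonds, data.frame(i = ca[sc$res], j = sc$particle,
                                   target = ifelse(sc$is_sg, .BOND_CA_SG, .BOND_CA_SC)))
  attr(lay, "bonds") <- bonds
  attr(lay, "sequence") <- sequence
  lay
}

# SG particle indices of a sequence's cysteines, in sequence order (C1..Cn)
.sg_particles <- function(lay) {
  lay$particle[lay$is_sg]
}

# map a pairing (2-col matrix of cysteine ordinals) to SG particle pairs
.ss_particle_pairs <- function(lay, pairing) {
  if (is.null(pairing) || NROW(pairing) == 0L) {
    return(matrix(integer(), ncol = 2))
  }
  sg <- .sg_particles(lay)
  pairing <- matrix(as.integer(pairing), ncol = 2)
  if (any(pairing < 1L | pairing > length(sg))) stop("cysteine ordinal out of range")
  cbind(sg[pairing[, 1]], sg[pairing[, 2]])
}

#' Lower/upper distance bound matrices for embedding
#'
#' Bonded pairs get tight bounds (target +/- 0.1 A); restrained pairs get
#' their NOE bounds; disulfide-constrained SG pairs get [1.9, 2.2] A; all
#' remaining pairs default to [3.0, n_res * 3.8] A. Upper bounds are then
#' smoothed by the triangle inequality (all-pairs shortest path).
#'
#' @param sequence one-letter residue string.
#' @param geo geometric restraints from [to_geometric()] (or NULL).
#' @param ss optional pairing: 2-column matrix of cysteine ordinals.
#' @return list with matrices \code{lower}, \code{upper} and the
#'   [coarse_layout()] as \code{layout}.
#' @export
bounds_matrix <- function(sequence, geo = NULL, ss = NULL) {
  lay <- coarse_layout(sequence)
  n <- nrow(lay)
  n_res <- max(lay$res)
  lower <- matrix(.REP_DIST, n, n)
  upper <- matrix(n_res * .BOND_CA_CA, n, n)
  diag(lower) <- 0; diag(upper) <- 0

  setb <- function(i, j, lo, up) {
    lower[i, j] <<- lo; lower[j, i] <<- lo
    upper[i, j] <<- up; upper[j, i] <<- up
  }
  bonds <- attr(lay, "bonds")
  for (k in seq_len(nrow(bonds))) {
    setb(bonds$i[k], bonds$j[k], bonds$target[k] - 0.1, bonds$target[k] + 0.1)
  }
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(bonds$i, bonds$j)] <- TRUE
  bonded[cbind(bonds$j, bonds$i)] <- TRUE
  if (!is.null(geo) && nrow(geo)) {
    for (k in seq_len(nrow(geo))) {
      i <- geo$p_i[k]; j <- geo$p_j[k]
      lo <- max(lower[i, j], geo$lower[k])
      up <- min(upper[i, j], geo$upper[k])
      if (up < lo) {
        if (bonded[i, j]) {
          up <- lo  # covalent geometry overrides an over-tight bound
        } else {
          stop("inconsistent distance bounds: restraint between particles ",
               i, " and ", j, " contradicts the lower bound")
        }
      }
      setb(i, j, lo, up)
    }
  }
  ssp <- .ss_particle_pairs(lay, ss)
  for (k in seq_len(nrow(ssp))) setb(ssp[k, 1], ssp[k, 2], 1.9, 2.2)

  # triangle smoothing of upper bounds (Floyd-Warshall, vectorized over k)
  for (k in seq_len(n)) {
    through <- outer(upper[, k], upper[k, ], "+")
    upper <- pmin(upper, through)
  }
  if (any(lower > upper + 1e-9)) {
    stop("inconsistent distance bounds: lower exceeds smoothed upper for ",
         sum(lower > upper + 1e-9) / 2, " pair(s)")
  }
  list(lower = lower, upper = upper, layout = lay)
}

#' Distance-geometry embedding
#'
#' Samples a trial distance matrix uniformly within the bounds and embeds it
#' in 3D by classical multidimensional scaling (top three spectral components
#' of the centered squared-distance Gram matrix). Because a sampled matrix is
#' generally not embeddable, the embed is then polished by alternating
#' projection: clip the realized distances back into the bounds, re-embed,
#' and repeat \code{refine_iters} times. Deterministic given the seed. A
#' degenerate (rank < 3) Gram matrix falls back to a seeded random coil,
#' flagged in the \code{fallback} attribute.
#'
#' @param bounds result of [bounds_matrix()].
#' @param seed integer seed.
#' @param refine_iters alternating-projection iterations (default 10).
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
dg_embed <- function(bounds, seed = 1L, refine_iters = 10L) {
  n <- nrow(bounds$lower)
  .with_seed(seed, {
    u <- matrix(runif(n * n), n, n)
    u[lower.tri(u)] <- t(u)[lower.tri(u)]
    d <- bounds$lower + u * (bounds$upper - bounds$lower)
    diag(d) <- 0
    fit <- stats::cmdscale(d, k = 3, eig = TRUE)
    if (ncol(fit$points) < 3 || sum(fit$eig > 1e-8) < 3) {
      # random-coil fallback: 3.8 A steps in random directions
      step <- matrix(stats::rnorm(n * 3), n, 3)
      step <- step / sqrt(rowSums(step^2)) * .BOND_CA_CA
      coords <- apply(step, 2, cumsum)
      attr(coords, "fallback") <- TRUE
      return(coords)
    }
    coords <- fit$points
    bound_sat <- function(x) {
      dd <- as.matrix(stats::dist(x))
      mean(dd >= bounds$lower - 1e-9 & dd <= bounds$upper + 1e-9)
    }
    best <- coords
    best_sat <- bound_sat(coords)
    for (it in seq_len(refine_iters)) {
      dd <- as.matrix(stats::dist(coords))
      dd <- pmin(pmax(dd, bounds$lower), bounds$upper)
      diag(dd) <- 0
      nxt <- stats::cmdscale(dd, k = 3)
      if (ncol(nxt) < 3) break
      coords <- nxt
      s <- bound_sat(coords)
      if (s > best_sat) {
        best_sat <- s
        best <- coords
      }
    }
    coords <- best
    attr(coords, "fallback") <- FALSE
    coords
  })
}

#' Annealing configuration
#'
#' @param t_start starting temperature (arbitrary energy units; default 2000).
#' @param t_end final temperature of the geometric schedule.
#' @param n_steps cooling steps; each step is one Metropolis sweep over all
#'   particles. The default 2000 is a scaled-down schedule suited to the
#'   coarse model (see the methods vignette).
#' @param move_max,move_min particle move amplitude (A) at the start/end of
#'   the schedule.
#' @param weights energy weights \code{c(noe, chain, rep, ss)}.
#' @param n_cycles annealing-plus-refinement cycles: cycle c >= 2 restarts
#'   the schedule from the previous result at 100^-(c-1) of the starting
#'   temperature with proportionally smaller moves (a cooling cycle followed
#'   by constraint-refinement quenches).
#' @param buffer refinement buffer in Angstrom: during embedding and
#'   annealing, restraint upper bounds are tightened by this margin so
#'   minima sit strictly inside the bounds instead of on them (the quadratic
#'   energy otherwise happily parks many restraints epsilon outside).
#'   Energies reported for model ranking always use the true bounds.
#' @param seed base integer seed.
#' @return list of class \code{anneal_config}.
#' @export
anneal_config <- function(t_start = 2000, t_end = 1, n_steps = 2000L,
                          move_max = 0.5, move_min = 0.05,
                          weights = c(noe = 10, chain = 10, rep = 1, ss = 10),
                          n_cycles = 2L, buffer = 0.1, seed = 1L) {
  stopifnot(t_start > 0, t_end > 0, n_steps >= 1L, all(weights >= 0),
            n_cycles >= 1L, buffer >= 0)
  structure(list(t_start = t_start, t_end = t_end, n_steps = as.integer(n_steps),
                 move_max = move_max, move_min = move_min,
                 weights = weights, n_cycles = as.integer(n_cycles),
                 buffer = buffer, seed = as.integer(seed)),
            class = "anneal_config")
}

# tighten restraint upper bounds by the refinement buffer
.buffered_geo <- function(geo, buffer) {
  if (is.null(geo) || !nrow(geo) || buffer <= 0) return(geo)
  geo$upper <- pmax(geo$lower + 0.2, geo$upper - buffer)
  geo
}

# assemble 0-based term arrays for the C++ kernels
.term_arrays <- function(lay, geo, ss) {
  bonds <- attr(lay, "bonds")
  ssp <- .ss_particle_pairs(lay, ss)
  list(
    bonds = cbind(bonds$i, bonds$j) - 1L,
    bond_t = bonds$target,
    rest = if (!is.null(geo) && nrow(geo)) cbind(geo$p_i, geo$p_j) - 1L else matrix(integer(), ncol = 2),
    rlo = if (!is.null(geo)) geo$lower else numeric(),
    rup = if (!is.null(geo)) geo$upper else numeric(),
    ss = ssp - 1L
  )
}

#' Restraint + chain energy of a model
#'
#' Flat-bottom quadratic NOE violations, harmonic chain bonds, soft-sphere
#' repulsion below 3 A between non-bonded particles, and harmonic disulfide
#' terms at 2.05 A. Zero when everything is satisfied; always non-negative.
#'
#' @param coords n x 3 coordinate matrix matching the layout of
#'   \code{sequence}.
#' @param sequence one-letter residue string.
#' @param geo geometric restraints from [to_geometric()] (or NULL).
#' @param ss optional pairing (2-column matrix of cysteine ordinals).
#' @param config an [anneal_config()] (supplies the weights).
#' @return scalar energy (arbitrary units).
#' @export
model_energy <- function(coords, sequence, geo = NULL, ss = NULL,
                         config = anneal_config()) {
  lay <- coarse_layout(sequence)
  stopifnot(nrow(coords) == nrow(lay))
  ta <- .term_arrays(lay, geo, ss)
  .cg_energy(as.matrix(coords), ta$bonds, ta$bond_t, ta$rest, ta$rlo, ta$rup,
             ta$ss, .SS_TARGET, unname(config$weights), .REP_DIST)
}

#' Refine a model by simulated annealing
#'
#' Seeded Metropolis Monte Carlo over single-particle Cartesian moves with a
#' geometric cooling schedule; the best-seen configuration is returned, so
#' the energy never exceeds that of an already-optimal start.
#'
#' @inheritParams model_energy
#' @param start n x 3 starting coordinates.
#' @return list with \code{coords}, \code{energy} (best seen) and
#'   \code{final_energy}.
#' @export
anneal_model <- function(start, sequence, geo = NULL, ss = NULL,
                         config = anneal_config()) {
  lay <- coarse_layout(sequence)
  stopifnot(nrow(start) == nrow(lay))
  ta <- .term_arrays(lay, geo, ss)
  n_cycles <- if (is.null(config$n_cycles)) 1L else config$n_cycles
  fit <- list(coords = as.matrix(start))
  for (cyc in seq_len(n_cycles)) {
    f <- 0.01^(cyc - 1)
    fit <- .cg_anneal(fit$coords, ta$bonds, ta$bond_t, ta$rest, ta$rlo, ta$rup,
                      ta$ss, .SS_TARGET, unname(config$weights), .REP_DIST,
                      config$t_start * f, config$t_end * f * 0.5^(cyc - 1),
                      config$n_steps,
                      config$move_max * 0.4^(cyc - 1),
                      config$move_min * 0.2^(cyc - 1),
                      config$seed + 5000L * (cyc - 1L))
  }
  fit
}

#' Generate a conformational ensemble
#'
#' Runs \code{n} independent embed + anneal cycles with seeds
#' \code{config$seed + 0 .. n-1} and records per-model energies, emulating
#' the calculate-many / keep-lowest protocol of restraint-based structure
#' determination.
#'
#' @param sequence one-letter residue string.
#' @param restraints a [noe_table()] (or NULL for restraint-free folding).
#' @param n number of models.
#' @param config an [anneal_config()].
#' @param ss optional disulfide pairing (2-column matrix of cysteine
#'   ordinals) enforced during folding.
#' @return object of class \code{cg_ensemble}: list with \code{models} (list
#'   of coordinate matrices), \code{energies}, \code{layout},
#'   \code{sequence}, \code{seeds} and \code{config}.
#' @export
generate_ensemble <- function(sequence, restraints = NULL, n = 100L,
                              config = anneal_config(), ss = NULL) {
  stopifnot(n >= 1L)
  geo <- if (!is.null(restraints)) to_geometric(restraints, sequence) else NULL
  buffer <- if (is.null(config$buffer)) 0 else config$buffer
  geo_t <- .buffered_geo(geo, buffer)
  bounds <- bounds_matrix(sequence, geo_t, ss)
  seeds <- config$seed + seq_len(n) - 1L
  models <- vector("list", n)
  energies <- numeric(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    start <- dg_embed(bounds, seed = seeds[i])
    fit <- anneal_model(start, sequence, geo_t, ss, cfg_i)
    models[[i]] <- fit$coords
    # rank by the energy against the true (unbuffered) bounds
    energies[i] <- model_energy(fit$coords, sequence, geo, ss, config)
  }
  structure(list(models = models, energies = energies, layout = bounds$layout,
                 sequence = sequence, seeds = seeds, config = config, ss = ss),
            class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat(sprintf("coarse ensemble: %d model(s) of %d particles (%d residues)\n",
              length(x$models), nrow(x$layout), max(x$layout$res)))
  cat(sprintf("energies: min %.3g, median %.3g, max %.3g\n",
              min(x$energies), stats::median(x$energies), max(x$energies)))
  invisible(x)
}

#' Keep the k lowest-energy models
#'
#' @param e a [generate_ensemble()] result.
#' @param k number of models to keep (1..n); ties broken by model index.
#' @return a \code{cg_ensemble} with k models, sorted by ascending energy.
#' @export
select_lowest <- function(e, k) {
  stopifnot(inherits(e, "cg_ensemble"))
  if (k < 1L || k > length(e$models)) stop("k must be in 1..", length(e$models))
  o <- order(e$energies, seq_along(e$energies))[seq_len(k)]
  e$models <- e$models[o]
  e$energies <- e$energies[o]
  e$seeds <- e$seeds[o]
  e
}

#' Fraction of restraints satisfied by a model
#'
#' @param coords n x 3 coordinates.
#' @param geo geometric restraints from [to_geometric()].
#' @return fraction in [0, 1] of restraints with lower <= d <= upper.
#' @export
restraint_satisfaction <- function(coords, geo) {
  if (is.null(geo) || !nrow(geo)) return(1)
  d <- sqrt(rowSums((coords[geo$p_i, , drop = FALSE] - coords[geo$p_j, , drop = FALSE])^2))
  mean(d >= geo$lower - 1e-9 & d <= geo$upper + 1e-9)
}

#' Backbone RMSD after optimal superposition
#'
#' Kabsch superposition of the CA particles in \code{range}, then the
#' root-mean-square deviation over those particles. Invariant under rigid
#' motion of either model.
#'
#' @param a,b coordinate matrices over the same particle layout.
#' @param layout the shared [coarse_layout()].
#' @param range optional residue span \code{c(from, to)}; default all.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, layout, range = NULL) {
  stopifnot(nrow(a) == nrow(layout), nrow(b) == nrow(layout))
  sel <- layout$type == "CA"
  if (!is.null(range)) sel <- sel & layout$res >= range[1] & layout$res <= range[2]
  x <- a[sel, , drop = FALSE]; y <- b[sel, , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 CA particles in range")
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  yr <- yc %*% rot
  sqrt(mean(rowSums((xc - yr)^2)))
}
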