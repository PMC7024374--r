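# Disulfide connectivity calling: average inter-cysteine sulfur distances
# over the lowest-energy models, score every perfect matching of cysteines,
# and optionally compare connectivities by constrained re-refinement.

#' Mean inter-cysteine sulfur distance matrix
#'
#' Averages the SG-SG distances of all cysteine pairs over the \code{k}
#' lowest-energy models of an ensemble.
#'
#' @param e a [generate_ensemble()] result.
#' @param k number of lowest-energy models to average (default 10).
#' @return object of class \code{ss_matrix}: list with \code{cys_positions}
#'   (residue numbers of C1..Cn) and \code{mean_dist} (symmetric matrix, A).
#' @export
ss_distance_matrix <- function(e, k = 10L) {
  stopifnot(inherits(e, "cg_ensemble"))
  if (k > length(e$models)) stop("ensemble has fewer than k = ", k, " models")
  sg <- .sg_particles(e$layout)
  if (length(sg) < 2L) stop("sequence has fewer than 2 cysteines")
  sel <- select_lowest(e, k)
  nc <- length(sg)
  acc <- matrix(0, nc, nc)
  for (m in sel$models) {
    xyz <- m[sg, , drop = FALSE]
    acc <- acc + as.matrix(stats::dist(xyz))
  }
  mean_dist <- acc / length(sel$models)
  dimnames(mean_dist) <- list(paste0("C", seq_len(nc)), paste0("C", seq_len(nc)))
  structure(list(cys_positions = e$layout$res[e$layout$is_sg],
                 mean_dist = mean_dist, k = k),
            class = "ss_matrix")
}

#' All perfect matchings of cysteines
#'
#' Enumerates the (n-1)!! pairings of n cysteines (15 for six, 105 for
#' eight), each as a 2-column matrix of cysteine ordinals with pairs sorted
#' by first index.
#'
#' @param n_cys even cysteine count >= 2.
#' @return list of 2-column integer matrices.
#' @examples
#' length(enumerate_pairings(6))  # 15
#' @export
enumerate_pairings <- function(n_cys) {
  if (n_cys < 2L || n_cys %% 2L != 0L) stop("n_cys must be even and >= 2")
  recurse <- function(idx) {
    if (!length(idx)) return(list(matrix(integer(), ncol = 2)))
    first <- idx[1]
    out <- list()
    for (p in idx[-1]) {
      rest <- recurse(setdiff(idx, c(first, p)))
      out <- c(out, lapply(rest, function(m) rbind(c(first, p), m)))
    }
    out
  }
  recurse(seq_len(n_cys))
}

#' Canonical label of a pairing
#'
#' @param pairs 2-column matrix of cysteine ordinals.
#' @return string like \code{"C1-C6/C2-C5/C3-C4"} (pairs sorted by first
#'   index, each pair ascending).
#' @export
pairing_label <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- t(apply(pairs, 1, sort))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  paste(sprintf("C%d-C%d", pairs[, 1], pairs[, 2]), collapse = "/")
}

#' Score all pairings against a distance matrix
#'
#' Each perfect matching is scored by the sum of mean SG-SG distances over
#' its pairs; the matching with the smallest sum is the called connectivity.
#' The gap between the best and second-best score is reported as a
#' confidence margin.
#'
#' @param m an [ss_distance_matrix()] result (or a plain symmetric matrix).
#' @return data.frame of class \code{pairing_scores} with columns
#'   \code{rank}, \code{label}, \code{score} (A); attributes \code{margin}
#'   (score gap rank 2 - rank 1) and \code{pairs} (list of matchings in rank
#'   order). Ties are broken lexicographically by label.
#' @export
score_pairings <- function(m) {
  dm <- if (inherits(m, "ss_matrix")) m$mean_dist else as.matrix(m)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  pairings <- enumerate_pairings(n)
  score <- vapply(pairings, function(p) sum(dm[p]), numeric(1))
  label <- vapply(pairings, pairing_label, character(1))
  o <- order(score, label)
  out <- data.frame(rank = seq_along(o), label = label[o], score = score[o])
  attr(out, "margin") <- if (nrow(out) > 1L) out$score[2] - out$score[1] else NA_real_
  attr(out, "pairs") <- pairings[o]
  class(out) <- c("pairing_scores", class(out))
  out
}

#' Compare candidate connectivities by constrained re-refinement
#'
#' Re-folds the peptide with each candidate disulfide pattern enforced and
#' summarizes the energies of the k lowest models, mirroring the control
#' calculation in which an alternative pattern yields overall less favorable
#' energies than the called one.
#'
#' @param sequence one-letter residue string.
#' @param restraints a [noe_table()].
#' @param candidates list of pairings (2-column matrices of cysteine
#'   ordinals).
#' @param n models per candidate.
#' @param k lowest-energy models summarized.
#' @param config an [anneal_config()]; each candidate uses the same seeds.
#' @return data.frame with \code{label}, \code{mean_lowk}, \code{min_energy},
#'   ranked by ascending \code{mean_lowk}.
#' @export
compare_connectivities <- function(sequence, restraints, candidates,
                                   n = 50L, k = 10L, config = anneal_config()) {
  stopifnot(length(candidates) >= 1L)
  rows <- lapply(candidates, function(cand) {
    e <- generate_ensemble(sequence, restraints, n = n, config = config, ss = cand)
    low <- select_lowest(e, min(k, n))
    data.frame(label = pairing_label(cand),
               mean_lowk = mean(low$energies),
               min_energy = min(low$energies))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_lowk, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
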