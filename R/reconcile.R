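# Reconciling measured and calculated monoisotopic masses: exhaustive
# search over modification multisets and short C-terminal extensions, and
# fragment-based localization of methionine oxidation.

#' Measured minus calculated mass difference
#'
#' @param measured measured monoisotopic mass (Da).
#' @param p a [peptide()] giving the calculated mass.
#' @return \code{measured - monoisotopic_mass(p)} in Da (full precision; the
#'   conventional report is 2 decimals).
#' @examples
#' p34 <- peptide(turgencin_sequences()["A34"],
#'                ss_bonds = list(c(8, 26), c(11, 29), c(17, 33)))
#' round(mass_delta(3705.79, p34), 2)  # 185.11
#' @export
mass_delta <- function(measured, p) {
  stopifnot(is.numeric(measured), length(measured) == 1L)
  measured - monoisotopic_mass(p)
}

# All candidate C-terminal extension strings up to max_len residues,
# in length-then-lexicographic enumeration order.
.extension_strings <- function(max_len) {
  aas <- sort(names(.AA_COMPOSITION))
  out <- ""
  cur <- ""
  for (l in seq_len(max_len)) {
    cur <- as.vector(outer(cur, aas, paste0))
    out <- c(out, cur)
  }
  out
}

#' Explain a measured-calculated mass difference
#'
#' Exhaustively enumerates hypotheses (C-terminal extension up to
#' \code{max_ext} residues) x (amidation) x (0..n Met-ox) x (0..n CAM-Cys)
#' and keeps those whose predicted mass lies within \code{tolerance} of the
#' measured mass. Met-ox counts are limited by the methionines available in
#' the peptide plus extension (minus already-oxidized ones); CAM by free
#' cysteines.
#'
#' Ranking: ascending |residual|; residuals closer than 1e-4 Da (below
#' achievable mass accuracy, where mass alone cannot discriminate) are
#' treated as tied and ordered by smaller extension mass (attributing the
#' difference to documented modification chemistry before extra sequence),
#' then shorter extension, then lexicographic extension, then parsimony
#' (fewer invoked changes). Exactly isobaric alternatives are therefore all
#' reported, in a deterministic order.
#'
#' @param measured measured monoisotopic mass (Da).
#' @param p base [peptide()] (typically the Edman-read sequence).
#' @param max_ext maximum C-terminal extension length (default 2).
#' @param tolerance match tolerance in Da (default 0.02).
#' @param families modification families to search over.
#' @return data.frame of class \code{delta_explanations} with columns
#'   \code{rank}, \code{extension}, \code{amidated}, \code{n_met_ox},
#'   \code{n_cam}, \code{total_delta}, \code{residual}, \code{n_changes}.
#'   Zero rows is a valid outcome (no explanation within tolerance).
#' @examples
#' p34 <- peptide(turgencin_sequences()["A34"],
#'                ss_bonds = list(c(8, 26), c(11, 29), c(17, 33)))
#' head(explain_delta(3705.79, p34))
#' @export
explain_delta <- function(measured, p, max_ext = 2L, tolerance = 0.02,
                          families = c("mox", "amide", "cam")) {
  stopifnot(inherits(p, "peptide"), tolerance > 0, max_ext >= 0L)
  base_mass <- monoisotopic_mass(p)
  res <- p$residues
  n_mox_used <- sum(p$mods$name == "mox")
  n_cam_used <- sum(p$mods$name == "cam")
  n_cys_bonded <- length(unlist(p$ss_bonds))
  mox_d <- .comp_mass(.MOD_COMP$mox)
  am_d <- .comp_mass(.MOD_COMP$amide)
  cam_d <- .comp_mass(.MOD_COMP$cam)

  exts <- .extension_strings(max_ext)
  ext_mass <- vapply(exts, function(e) {
    if (!nzchar(e)) 0 else sum(vapply(strsplit(e, "")[[1]], .residue_mass, numeric(1)))
  }, numeric(1))
  ext_nmet <- vapply(exts, function(e) lengths(regmatches(e, gregexpr("M", e))), integer(1))
  ext_ncys <- vapply(exts, function(e) lengths(regmatches(e, gregexpr("C", e))), integer(1))

  amide_opts <- if ("amide" %in% families && p$c_term == "free") c(FALSE, TRUE) else FALSE

  rows <- vector("list", 0L)
  for (ei in seq_along(exts)) {
    free_met <- sum(res == "M") - n_mox_used + ext_nmet[ei]
    free_cys <- sum(res == "C") - n_cam_used - n_cys_bonded + ext_ncys[ei]
    mox_range <- if ("mox" %in% families) 0:free_met else 0L
    cam_range <- if ("cam" %in% families) 0:free_cys else 0L
    for (am in amide_opts) {
      for (k in mox_range) {
        for (cc in cam_range) {
          delta <- ext_mass[ei] + am * am_d + k * mox_d + cc * cam_d
          resid <- measured - (base_mass + delta)
          if (abs(resid) <= tolerance) {
            rows[[length(rows) + 1L]] <- data.frame(
              extension = exts[ei], amidated = am, n_met_ox = k, n_cam = cc,
              total_delta = delta, residual = resid,
              n_changes = nchar(exts[ei]) + am + k + cc,
              ext_mass = ext_mass[ei],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(), extension = character(),
                      amidated = logical(), n_met_ox = integer(),
                      n_cam = integer(), total_delta = numeric(),
                      residual = numeric(), n_changes = integer())
    class(out) <- c("delta_explanations", class(out))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- do.call(rbind, rows)

  # group residual ties at 0.1 mDa by walking the sorted residuals
  o <- order(abs(out$residual))
  out <- out[o, , drop = FALSE]
  grp <- integer(nrow(out))
  g <- 1L; start <- abs(out$residual[1])
  for (i in seq_len(nrow(out))) {
    if (abs(out$residual[i]) > start + 1e-4) {
      g <- g + 1L; start <- abs(out$residual[i])
    }
    grp[i] <- g
  }
  out <- out[order(grp, out$ext_mass, nchar(out$extension), out$extension,
                   out$n_changes, abs(out$residual)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$ext_mass <- NULL
  rownames(out) <- NULL
  out <- out[, c("rank", "extension", "amidated", "n_met_ox", "n_cam",
                 "total_delta", "residual", "n_changes")]
  class(out) <- c("delta_explanations", class(out))
  attr(out, "empty") <- FALSE
  out
}

#' Localize methionine oxidation from fragment ions
#'
#' For each candidate single Met-ox placement, counts the observed singly
#' charged b/y fragment m/z values that match the placement's theoretical
#' fragments within tolerance. An observed b5 at 575.28 for a peptide with
#' Met at position 5 supports oxidation at 5 (GIKEM+O) and not at a later
#' methionine.
#'
#' @param p a linear [peptide()] without existing Met-ox.
#' @param observed_fragments data.frame with columns \code{series}
#'   (\code{"b"}/\code{"y"}), \code{index}, \code{mz}.
#' @param tolerance m/z tolerance in Da (default 0.02).
#' @return data.frame with columns \code{position} (Met position) and
#'   \code{support}, ranked by decreasing support, ties by position.
#' @export
localize_oxidation <- function(p, observed_fragments, tolerance = 0.02) {
  stopifnot(inherits(p, "peptide"))
  mets <- which(p$residues == "M")
  if (!length(mets)) stop("peptide contains no methionine")
  obs <- observed_fragments
  if (nrow(obs) && (any(!obs$series %in% c("b", "y")) ||
                    any(obs$index < 1L | obs$index > length(p$residues)))) {
    stop("observed fragment with invalid series or index out of range")
  }
  support <- vapply(mets, function(m) {
    cand <- peptide(paste(p$residues, collapse = ""), c_term = p$c_term,
                    mods = rbind(p$mods, data.frame(name = "mox", pos = m)),
                    ss_bonds = p$ss_bonds)
    theo <- fragment_ions(cand, max_charge = 1L)
    if (!nrow(obs)) return(0L)
    sum(vapply(seq_len(nrow(obs)), function(i) {
      hit <- theo$series == obs$series[i] & theo$index == obs$index[i]
      any(abs(theo$mz[hit] - obs$mz[i]) <= tolerance)
    }, logical(1)))
  }, integer(1))
  out <- data.frame(position = mets, support = support)
  out[order(-out$support, out$position), , drop = FALSE]
}
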