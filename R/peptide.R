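# Peptide objects and exact mass chemistry.

#' Construct a peptide
#'
#' A peptide is an ordered residue string plus terminal states, site-specific
#' modifications and an optional disulfide topology. All mass arithmetic in
#' the package operates on this object.
#'
#' @param sequence One-letter residue string (20 standard codes).
#' @param c_term \code{"free"} or \code{"amide"} (C-terminal amidation,
#'   -0.984016 Da).
#' @param mods data.frame with columns \code{name} (\code{"mox"} or
#'   \code{"cam"}) and \code{pos} (1-based residue position), or \code{NULL}.
#' @param ss_bonds list of length-2 integer vectors, each a pair of distinct
#'   cysteine positions; every cysteine may appear in at most one bridge.
#'   Each bridge contributes -2.015650 Da.
#' @param n_term \code{"free"} (only state currently supported).
#' @return An object of class \code{peptide}.
#' @examples
#' p <- peptide("GIKEM", mods = data.frame(name = "mox", pos = 5))
#' monoisotopic_mass(p)
#' @export
peptide <- function(sequence, c_term = c("free", "amide"), mods = NULL,
                    ss_bonds = list(), n_term = "free") {
  c_term <- match.arg(c_term)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.AA_COMPOSITION))
  if (length(bad)) stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (!identical(n_term, "free")) stop("only free N-terminus is supported")
  n <- length(res)

  if (is.null(mods)) mods <- data.frame(name = character(), pos = integer())
  mods <- data.frame(name = as.character(mods$name), pos = as.integer(mods$pos))
  for (k in seq_len(nrow(mods))) {
    nm <- mods$name[k]; pos <- mods$pos[k]
    if (!nm %in% c("mox", "cam")) stop("unknown site modification: ", nm)
    if (is.na(pos) || pos < 1L || pos > n) stop("modification position out of range: ", pos)
    if (nm == "mox" && res[pos] != "M") stop("mox at position ", pos, " requires Met, found ", res[pos])
    if (nm == "cam" && res[pos] != "C") stop("cam at position ", pos, " requires Cys, found ", res[pos])
  }
  if (anyDuplicated(mods)) stop("duplicated modification entries")

  ss_bonds <- lapply(ss_bonds, function(b) sort(as.integer(b)))
  used <- integer()
  for (b in ss_bonds) {
    if (length(b) != 2L || b[1] == b[2]) stop("a disulfide bridge needs two distinct positions")
    if (any(b < 1L | b > n)) stop("disulfide position out of range")
    if (any(res[b] != "C")) stop("disulfide bridge on non-cysteine position(s): ", paste(b, collapse = "-"))
    if (any(b %in% used)) stop("cysteine reused in two bridges: ", paste(intersect(b, used), collapse = ","))
    used <- c(used, b)
  }

  structure(list(residues = res, n_term = n_term, c_term = c_term,
                 mods = mods, ss_bonds = ss_bonds),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("peptide: %s (%d aa, C-term %s", paste(x$residues, collapse = ""),
              length(x$residues), x$c_term))
  if (nrow(x$mods)) cat(sprintf(", %d site mod(s)", nrow(x$mods)))
  if (length(x$ss_bonds)) cat(sprintf(", %d S-S", length(x$ss_bonds)))
  cat(")\n")
  invisible(x)
}

#' Parse a peptide from sequence and modification strings
#'
#' The modification string is a comma-separated list of tokens:
#' \code{amide}, \code{Mox@<pos>}, \code{CAM@<pos>}, and
#' \code{SS:<i>-<j>[,<i>-<j>...]} (bare \code{i-j} tokens following an
#' \code{SS:} token are further bridges).
#'
#' @param text one-letter sequence string.
#' @param mod_spec modification string, possibly empty.
#' @return A [peptide()].
#' @examples
#' parse_peptide("GIKEM", "Mox@5")
#' parse_peptide("GACGC", "amide,SS:2-5")
#' @export
parse_peptide <- function(text, mod_spec = "") {
  tokens <- if (nzchar(trimws(mod_spec))) trimws(strsplit(mod_spec, ",")[[1]]) else character()
  c_term <- "free"
  mods <- data.frame(name = character(), pos = integer())
  ss <- list()
  in_ss <- FALSE
  for (tok in tokens) {
    if (tok == "amide") {
      c_term <- "amide"; in_ss <- FALSE
    } else if (grepl("^Mox@[0-9]+$", tok)) {
      mods <- rbind(mods, data.frame(name = "mox", pos = as.integer(sub("^Mox@", "", tok))))
      in_ss <- FALSE
    } else if (grepl("^CAM@[0-9]+$", tok)) {
      mods <- rbind(mods, data.frame(name = "cam", pos = as.integer(sub("^CAM@", "", tok))))
      in_ss <- FALSE
    } else if (grepl("^SS:[0-9]+-[0-9]+$", tok)) {
      pr <- as.integer(strsplit(sub("^SS:", "", tok), "-")[[1]])
      ss <- c(ss, list(pr)); in_ss <- TRUE
    } else if (in_ss && grepl("^[0-9]+-[0-9]+$", tok)) {
      ss <- c(ss, list(as.integer(strsplit(tok, "-")[[1]])))
    } else {
      stop("cannot parse modification token: '", tok, "'")
    }
  }
  peptide(text, c_term = c_term, mods = mods, ss_bonds = ss)
}

#' Elemental composition of a peptide
#'
#' Residue compositions plus one water for the termini, plus the signed
#' composition deltas of all modifications (amidation, Met-ox, CAM,
#' disulfides). The mass implied by the returned map equals
#' [monoisotopic_mass()] to within 1e-6 Da by construction.
#'
#' @param p a [peptide()].
#' @return Named integer vector of element counts.
#' @export
elemental_composition <- function(p) {
  stopifnot(inherits(p, "peptide"))
  comp <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  add <- function(comp, delta) {
    comp[names(delta)] <- comp[names(delta)] + delta
    comp
  }
  for (r in p$residues) comp <- add(comp, .AA_COMPOSITION[[r]])
  comp <- add(comp, .WATER_COMP)
  if (p$c_term == "amide") comp <- add(comp, .MOD_COMP$amide)
  for (k in seq_len(nrow(p$mods))) comp <- add(comp, .MOD_COMP[[p$mods$name[k]]])
  for (b in p$ss_bonds) comp <- add(comp, .MOD_COMP$ss)
  comp[comp != 0]
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water (18.010565 Da), plus modification
#' deltas: -0.984016 for C-terminal amidation, +15.994915 per Met sulfoxide,
#' +57.021464 per carbamidomethyl-Cys and -2.015650 per disulfide bridge.
#'
#' @param p a [peptide()].
#' @return Mass in Da.
#' @examples
#' tg <- turgencin_sequences()
#' p <- parse_peptide(tg["B"], "amide,SS:7-31,11-27,16-24")
#' round(monoisotopic_mass(p), 2)  # 3538.58
#' @export
monoisotopic_mass <- function(p) {
  stopifnot(inherits(p, "peptide"))
  m <- sum(vapply(p$residues, .residue_mass, numeric(1))) + .WATER_MASS
  if (p$c_term == "amide") m <- m + .comp_mass(.MOD_COMP$amide)
  if (nrow(p$mods)) {
    m <- m + sum(vapply(p$mods$name, function(nm) .comp_mass(.MOD_COMP[[nm]]), numeric(1)))
  }
  m + length(p$ss_bonds) * .comp_mass(.MOD_COMP$ss)
}

#' Isotope pattern of an elemental composition
#'
#' Convolves per-element isotope abundance vectors (each element's
#' distribution over neutron offsets is the n-fold convolution of its natural
#' single-atom abundances) and truncates to the requested number of peaks,
#' renormalizing. The A+0 abundance is the product of the lightest-isotope
#' probabilities.
#'
#' @param comp named element-count vector, e.g. from
#'   [elemental_composition()].
#' @param n_peaks number of isotopologue peaks to keep (>= 1).
#' @return Object of class \code{isotope_pattern}: list with integer
#'   \code{offsets} and \code{abundances} summing to 1.
#' @examples
#' isotope_distribution(c(C = 1), 2)
#' @export
isotope_distribution <- function(comp, n_peaks = 10L) {
  stopifnot(n_peaks >= 1L)
  comp <- comp[comp != 0]
  if (any(comp < 0)) stop("negative element counts")
  bad <- setdiff(names(comp), names(.ISOTOPE_ABUNDANCE))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  keep <- n_peaks + 4L  # working margin before final truncation

  conv <- function(a, b) {
    out <- numeric(min(length(a) + length(b) - 1L, keep))
    for (i in seq_along(a)) {
      jmax <- min(length(b), keep - i + 1L)
      if (jmax >= 1L) {
        idx <- i:(i + jmax - 1L)
        out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
      }
    }
    out
  }
  pow <- function(v, n) { # n-fold self-convolution by squaring
    acc <- 1
    base <- v
    while (n > 0L) {
      if (n %% 2L == 1L) acc <- conv(acc, base)
      n <- n %/% 2L
      if (n > 0L) base <- conv(base, base)
    }
    acc
  }
  dist <- 1
  for (el in names(comp)) dist <- conv(dist, pow(.ISOTOPE_ABUNDANCE[[el]], comp[[el]]))
  dist <- dist[seq_len(min(n_peaks, length(dist)))]
  structure(list(offsets = seq_along(dist) - 1L, abundances = dist / sum(dist)),
            class = "isotope_pattern")
}

#' b and y fragment ions
#'
#' Theoretical fragment masses for a linear peptide: \eqn{b_i} is the sum of
#' the first i residue masses (plus located modification deltas) plus a
#' proton; \eqn{y_i} additionally carries the water of the C-terminus and any
#' C-terminal amidation. For charge z, m/z = (M + z * 1.007276) / z. The
#' singly charged complementarity b_i + y_(n-i) = M + 2 * proton holds.
#'
#' @param p a linear [peptide()] (no disulfide bonds).
#' @param series \code{"b"}, \code{"y"} or both.
#' @param max_charge maximum charge state to enumerate.
#' @return data.frame with columns \code{ion}, \code{series}, \code{index},
#'   \code{charge}, \code{mz}.
#' @examples
#' fragment_ions(peptide("GIKEM"), "b")  # b5 at 559.29
#' @export
fragment_ions <- function(p, series = c("b", "y"), max_charge = 1L) {
  stopifnot(inherits(p, "peptide"))
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (length(p$ss_bonds)) stop("fragment enumeration requires a peptide without disulfide bonds")
  n <- length(p$residues)
  rm <- vapply(p$residues, .residue_mass, numeric(1))
  moddelta <- numeric(n)
  for (k in seq_len(nrow(p$mods))) {
    moddelta[p$mods$pos[k]] <- moddelta[p$mods$pos[k]] + .comp_mass(.MOD_COMP[[p$mods$name[k]]])
  }
  persite <- rm + moddelta
  cterm_delta <- if (p$c_term == "amide") .comp_mass(.MOD_COMP$amide) else 0

  rows <- list()
  for (s in series) {
    for (i in seq_len(n - 1L)) {
      neutral <- if (s == "b") {
        sum(persite[seq_len(i)])
      } else {
        sum(persite[(n - i + 1L):n]) + .WATER_MASS + cterm_delta
      }
      for (z in seq_len(max_charge)) {
        rows[[length(rows) + 1L]] <- data.frame(
          ion = sprintf("%s%d%s", s, i, if (z > 1) paste0("^", z, "+") else ""),
          series = s, index = i, charge = z,
          mz = (neutral + z * .PROTON_MASS) / z)
      }
    }
    # full-length ion (b_n / y_n): y_n is [M+H]+ of the peptide
    full <- sum(persite) + if (s == "y") .WATER_MASS + cterm_delta else 0
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ion = sprintf("%s%d%s", s, n, if (z > 1) paste0("^", z, "+") else ""),
        series = s, index = n, charge = z,
        mz = (full + z * .PROTON_MASS) / z)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: positive contributions
#' from the free N-terminus and H/K/R side chains, negative from the free
#' C-terminus (absent when amidated) and D/E/C/Y side chains. Cysteines
#' engaged in disulfide bridges or carbamidomethylated are not ionizable.
#'
#' @param p a [peptide()].
#' @param pH pH value in (0, 14).
#' @param pka named pKa vector, see [default_pka()].
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(p, pH, pka = default_pka()) {
  stopifnot(inherits(p, "peptide"), pH > 0, pH < 14)
  res <- p$residues
  blocked <- c(unlist(p$ss_bonds), p$mods$pos[p$mods$name == "cam"])
  pos_groups <- c(pka[["n_term"]],
                  pka[match(res[res %in% c("H", "K", "R")], names(pka))])
  acid_res <- which(res %in% c("D", "E", "C", "Y") & !(seq_along(res) %in% blocked))
  neg_groups <- pka[match(res[acid_res], names(pka))]
  if (p$c_term == "free") neg_groups <- c(pka[["c_term"]], neg_groups)
  sum(1 / (1 + 10^(pH - pos_groups))) - sum(1 / (1 + 10^(neg_groups - pH)))
}

#' Isoelectric point
#'
#' pH at which the net charge is zero, found by bisection of [net_charge()]
#' over (0, 14) to |charge| < 1e-4. The charge function is monotone
#' non-increasing in pH, so the root is unique.
#'
#' @inheritParams net_charge
#' @return pI in pH units (unrounded; the conventional report is 2 decimals).
#' @examples
#' round(isoelectric_point(peptide(turgencin_sequences()["A"])), 2)  # 9.24
#' @export
isoelectric_point <- function(p, pka = default_pka()) {
  lo <- 1e-9; hi <- 14 - 1e-9
  clo <- net_charge(p, lo, pka); chi <- net_charge(p, hi, pka)
  if (clo <= 0 || chi >= 0) {
    stop("no sign change of net charge over (0, 14); peptide lacks an ionizable group of one sign")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    cm <- net_charge(p, mid, pka)
    if (abs(cm) < 1e-4) return(mid)
    if (cm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
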