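# NOE-derived distance restraints: class bounds, mapping onto the
# coarse-grained model, scalar couplings, and NOE-pattern helix propensity.

.NOE_UPPER <- c(strong = 2.5, medium = 3.7, weak = 5.0)
.NOE_LOWER <- 1.8  # van der Waals contact
.ATOM_TAGS <- c("HN", "HA", "HB", "SC")

#' Distance bounds for an NOE intensity class
#'
#' Strong, medium and weak cross peaks carry upper-limit constraints of 2.5,
#' 3.7 and 5.0 Angstrom respectively; the lower bound is the van der Waals
#' contact distance of 1.8 Angstrom.
#'
#' @param cls \code{"strong"}, \code{"medium"} or \code{"weak"}.
#' @return Named numeric vector \code{c(lower =, upper =)} in Angstrom.
#' @examples
#' classify_noe("strong")
#' @export
classify_noe <- function(cls) {
  if (length(cls) != 1L || !cls %in% names(.NOE_UPPER)) {
    stop("unknown NOE class: ", paste(cls, collapse = ","))
  }
  c(lower = .NOE_LOWER, upper = unname(.NOE_UPPER[cls]))
}

#' Build a restraint table
#'
#' @param df data.frame with columns \code{res_i}, \code{atom_i},
#'   \code{res_j}, \code{atom_j}, \code{class} and optionally \code{upper}
#'   (filled from class when missing). Atoms are tags in HN, HA, HB, SC.
#' @param sequence_length number of residues the indices refer to.
#' @return data.frame of class \code{restraint_table} with columns
#'   \code{res_i}, \code{atom_i}, \code{res_j}, \code{atom_j}, \code{class},
#'   \code{lower}, \code{upper} and attribute \code{sequence_length}.
#' @export
noe_table <- function(df, sequence_length) {
  need <- c("res_i", "atom_i", "res_j", "atom_j", "class")
  if (!all(need %in% names(df))) stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$res_i <- as.integer(df$res_i); df$res_j <- as.integer(df$res_j)
  if (nrow(df)) {
    if (any(df$res_i < 1L | df$res_i > sequence_length |
            df$res_j < 1L | df$res_j > sequence_length)) {
      stop("residue index outside 1..", sequence_length)
    }
    if (any(!df$atom_i %in% .ATOM_TAGS) || any(!df$atom_j %in% .ATOM_TAGS)) {
      stop("unknown atom tag; expected one of ", paste(.ATOM_TAGS, collapse = ", "))
    }
    if (any(!df$class %in% names(.NOE_UPPER))) {
      stop("unknown NOE class: ", paste(unique(setdiff(df$class, names(.NOE_UPPER))), collapse = ","))
    }
  }
  if (is.null(df$upper)) df$upper <- unname(.NOE_UPPER[df$class])
  df$upper[is.na(df$upper)] <- unname(.NOE_UPPER[df$class[is.na(df$upper)]])
  df$lower <- rep(.NOE_LOWER, nrow(df))
  out <- df[, c("res_i", "atom_i", "res_j", "atom_j", "class", "lower", "upper")]
  attr(out, "sequence_length") <- as.integer(sequence_length)
  class(out) <- c("restraint_table", class(out))
  out
}

#' Restraint counts by sequence separation
#'
#' @param t a [noe_table()].
#' @return Named integer vector: \code{intra} (|i-j| = 0), \code{sequential}
#'   (= 1), \code{medium_range} (2..4), \code{long_range} (>= 5) and
#'   \code{total}.
#' @export
restraint_categories <- function(t) {
  stopifnot(inherits(t, "restraint_table"))
  sep <- abs(t$res_i - t$res_j)
  c(intra = sum(sep == 0L),
    sequential = sum(sep == 1L),
    medium_range = sum(sep >= 2L & sep <= 4L),
    long_range = sum(sep >= 5L),
    total = length(sep))
}

#' Map proton restraints onto coarse-grained particles
#'
#' Backbone protons (HN, HA) map to the residue's CA particle; side-chain
#' protons (HB, SC) map to the side-chain particle. Because the model
#' particle sits away from the proton, the upper bound is relaxed by a
#' pseudo-particle correction: +1.0 Angstrom when both atoms are backbone,
#' +1.5 when a side chain is involved (the larger offset dominates).
#'
#' @param t a [noe_table()].
#' @param sequence one-letter sequence (needed to reject side-chain
#'   restraints on glycine and to index particles).
#' @param corrections numeric vector \code{c(backbone =, sidechain =)} in
#'   Angstrom.
#' @return data.frame with particle indices \code{p_i}, \code{p_j} (into
#'   [coarse_layout()] of the sequence) and corrected \code{lower},
#'   \code{upper}.
#' @export
to_geometric <- function(t, sequence,
                         corrections = c(backbone = 1.0, sidechain = 1.5)) {
  stopifnot(inherits(t, "restraint_table"))
  lay <- coarse_layout(sequence)
  if (attr(t, "sequence_length") != max(lay$res)) {
    stop("restraint table indexed to ", attr(t, "sequence_length"),
         " residues but sequence has ", max(lay$res))
  }
  res <- strsplit(sequence, "")[[1]]
  map1 <- function(resno, atom) {
    backbone <- atom %in% c("HN", "HA")
    if (!backbone && res[resno] == "G") {
      stop("side-chain restraint on glycine at residue ", resno)
    }
    type <- if (backbone) "CA" else "SC"
    list(p = which(lay$res == resno & lay$type == type),
         corr = if (backbone) corrections[["backbone"]] else corrections[["sidechain"]])
  }
  n <- nrow(t)
  p_i <- integer(n); p_j <- integer(n); corr <- numeric(n)
  for (k in seq_len(n)) {
    a <- map1(t$res_i[k], t$atom_i[k])
    b <- map1(t$res_j[k], t$atom_j[k])
    p_i[k] <- a$p; p_j[k] <- b$p
    corr[k] <- max(a$corr, b$corr)
  }
  data.frame(p_i = p_i, p_j = p_j, lower = t$lower, upper = t$upper + corr)
}

#' Karplus relation for 3J(HN-HA)
#'
#' \eqn{J(\phi) = A\cos^2(\phi - \theta) + B\cos(\phi - \theta) + C} with the
#' conventional 60 degree offset. The default coefficients are calibrated so
#' the curve passes through the two structural anchors exactly: 4 Hz at
#' phi = -60 (alpha helix) and 9 Hz at phi = -120 (beta sheet), with the
#' usual 1.6 Hz baseline; all three are arguments for users preferring a
#' published parameterization.
#'
#' @param phi backbone phi dihedral in degrees, in [-180, 180].
#' @param A,B,C Karplus coefficients in Hz.
#' @param offset angular offset in degrees.
#' @return Coupling constant in Hz.
#' @examples
#' karplus_j(-60)   # 4 Hz
#' karplus_j(-120)  # 9 Hz
#' @export
karplus_j <- function(phi, A = 5.2, B = -2.2, C = 1.60, offset = 60) {
  stopifnot(all(phi >= -180 & phi <= 180))
  th <- (phi - offset) * pi / 180
  A * cos(th)^2 + B * cos(th) + C
}

#' Classify a 3J(HN-HA) coupling
#'
#' Couplings below 6 Hz indicate helix-like phi angles, above 7.5 Hz
#' sheet-like ones; the 6.0-7.5 Hz band indicates conformational averaging
#' between the two.
#'
#' @param j coupling constant(s) in Hz, in (0, 12).
#' @return factor with levels \code{helix}, \code{averaged}, \code{sheet}.
#' @examples
#' j_classify(c(4, 6.5, 9))
#' @export
j_classify <- function(j) {
  stopifnot(all(j > 0 & j < 12))
  factor(ifelse(j < 6.0, "helix", ifelse(j > 7.5, "sheet", "averaged")),
         levels = c("helix", "averaged", "sheet"))
}

#' NOE-pattern helix propensity
#'
#' A residue scores \code{w[1]} when the sequential HN(n-1)-HN(n) cross peak
#' is present and stronger than (or present without) the HA(n-1)-HN(n) peak
#' -- the classic alpha-helix signature -- and \code{w[2]} when an
#' HA(i)-HN(i+3) contact covers it. Contiguous runs of score >= 1 spanning at
#' least 3 residues are reported as helix segments.
#'
#' @param t a [noe_table()].
#' @param w numeric length-2 weights, default \code{c(1, 1)}.
#' @return list with \code{score} (numeric per residue) and \code{segments}
#'   (data.frame \code{start}, \code{end}).
#' @export
helix_propensity <- function(t, w = c(1, 1)) {
  stopifnot(inherits(t, "restraint_table"), length(w) == 2L)
  n <- attr(t, "sequence_length")
  rank <- c(weak = 1L, medium = 2L, strong = 3L)
  lo <- pmin(t$res_i, t$res_j); hi <- pmax(t$res_i, t$res_j)
  # atom tag on the lower/higher residue of each restraint
  atom_lo <- ifelse(t$res_i <= t$res_j, t$atom_i, t$atom_j)
  atom_hi <- ifelse(t$res_i <= t$res_j, t$atom_j, t$atom_i)

  score <- numeric(n)
  for (m in 2:max(2L, n)) {
    if (n < 2L) break
    seqsel <- lo == m - 1L & hi == m
    nn <- t$class[seqsel & atom_lo == "HN" & atom_hi == "HN"]
    an <- t$class[seqsel & atom_lo == "HA" & atom_hi == "HN"]
    nn_rank <- if (length(nn)) max(rank[nn]) else 0L
    an_rank <- if (length(an)) max(rank[an]) else 0L
    if (nn_rank > 0L && nn_rank > an_rank) score[m] <- score[m] + w[1]
  }
  i3 <- which(hi - lo == 3L & atom_lo == "HA" & atom_hi == "HN")
  for (k in i3) score[lo[k]:hi[k]] <- score[lo[k]:hi[k]] + w[2]

  in_seg <- score >= 1
  r <- rle(in_seg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  list(score = score,
       segments = data.frame(start = starts[keep], end = ends[keep]))
}

#' Read / write restraint tables
#'
#' Tab-separated format with columns \code{res_i atom_i res_j atom_j class
#' [upper]}; write followed by read reproduces the table exactly.
#'
#' @param path file path.
#' @param sequence_length residue count the table is indexed to; when
#'   reading, taken from the \code{# sequence_length=} header if present.
#' @return [noe_table()] for \code{read_restraints}; invisibly \code{path}
#'   for \code{write_restraints}.
#' @export
read_restraints <- function(path, sequence_length = NULL) {
  lines <- readLines(path)
  hdr <- grep("^# sequence_length=", lines, value = TRUE)
  if (is.null(sequence_length)) {
    if (!length(hdr)) stop("sequence_length not given and no header in file")
    sequence_length <- as.integer(sub("^# sequence_length=", "", hdr[1]))
  }
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) return(noe_table(data.frame(res_i = integer(), atom_i = character(),
                                                 res_j = integer(), atom_j = character(),
                                                 class = character()), sequence_length))
  fields <- strsplit(body, "\t| +")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 5L) stop("malformed restraint row at data line ", i, ": '", body[i], "'")
    ri <- suppressWarnings(as.integer(f[1])); rj <- suppressWarnings(as.integer(f[3]))
    if (is.na(ri) || is.na(rj)) stop("malformed restraint row at data line ", i, ": '", body[i], "'")
    data.frame(res_i = ri, atom_i = f[2], res_j = rj, atom_j = f[4], class = f[5],
               upper = if (length(f) >= 6L) as.numeric(f[6]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  noe_table(do.call(rbind, rows), sequence_length)
}

#' @rdname read_restraints
#' @param t a [noe_table()] to write.
#' @export
write_restraints <- function(t, path) {
  stopifnot(inherits(t, "restraint_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sequence_length=%d", attr(t, "sequence_length")), con)
  writeLines("# res_i\tatom_i\tres_j\tatom_j\tclass\tupper", con)
  if (nrow(t)) {
    writeLines(sprintf("%d\t%s\t%d\t%s\t%s\t%.2f",
                       t$res_i, t$atom_i, t$res_j, t$atom_j, t$class, t$upper), con)
  }
  invisible(path)
}
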