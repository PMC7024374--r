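# Elemental and residue-level chemistry tables.
#
# All residue monoisotopic masses are derived from elemental compositions and
# the IUPAC monoisotopic element masses below, so composition and mass can
# never drift apart.

.ELEMENT_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.007276466879

# Isotope abundance vectors indexed by neutron offset 0,1,2,... (NIST values).
.ISOTOPE_ABUNDANCE <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

# Residue (amino acid minus water) elemental compositions.
.AA_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.AA_THREE <- c(
  G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL", T = "THR",
  C = "CYS", L = "LEU", I = "ILE", N = "ASN", D = "ASP", Q = "GLN",
  K = "LYS", E = "GLU", M = "MET", H = "HIS", F = "PHE", R = "ARG",
  Y = "TYR", W = "TRP"
)

.comp_mass <- function(comp) {
  if (length(comp) == 0L) return(0)
  bad <- setdiff(names(comp), names(.ELEMENT_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(.ELEMENT_MASS[names(comp)] * comp)
}

.WATER_COMP <- c(H = 2, O = 1)
.WATER_MASS <- .comp_mass(.WATER_COMP)   # 18.010565

# Built-in modification composition deltas (signed element counts).
.MOD_COMP <- list(
  mox   = c(O = 1),                # Met -> Met sulfoxide, +15.994915
  amide = c(O = -1, N = 1, H = 1), # C-terminal -OH -> -NH2, -0.984016
  ss    = c(H = -2),               # one disulfide bridge, -2.015650
  cam   = c(C = 2, H = 3, N = 1, O = 1) # carbamidomethyl-Cys, +57.021464
)

#' Amino acid residue table
#'
#' Residue-level (water-free) monoisotopic masses and elemental formulas for
#' the 20 standard amino acids, as used by all mass arithmetic in the package.
#'
#' @return A data.frame with columns \code{code}, \code{three},
#'   \code{mono_mass} (Da) and \code{formula}.
#' @examples
#' amino_acids()[amino_acids()$code == "G", ]
#' @export
amino_acids <- function() {
  codes <- names(.AA_COMPOSITION)
  data.frame(
    code = codes,
    three = unname(.AA_THREE[codes]),
    mono_mass = vapply(.AA_COMPOSITION, .comp_mass, numeric(1)),
    formula = vapply(.AA_COMPOSITION, function(x) {
      paste0(names(x), x, collapse = "")
    }, character(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

.residue_mass <- function(code) {
  comp <- .AA_COMPOSITION[[code]]
  if (is.null(comp)) stop("unknown residue code: ", code)
  .comp_mass(comp)
}

#' Built-in modification mass deltas
#'
#' Monoisotopic mass deltas of the modifications the package knows about:
#' methionine sulfoxide (\code{mox}), C-terminal amidation (\code{amide}),
#' one disulfide bridge (\code{ss}) and carbamidomethyl cysteine (\code{cam}).
#' Deltas are derived from elemental composition changes.
#'
#' @return Named numeric vector of deltas in Da.
#' @examples
#' modification_deltas()["mox"]  # +15.994915
#' @export
modification_deltas <- function() {
  vapply(.MOD_COMP, .comp_mass, numeric(1))
}

#' Default pKa set for charge and pI calculations
#'
#' An ExPASy/Bjellqvist-style set of acid dissociation constants for the
#' ionizable groups of a peptide. Values are in pH units and can be replaced
#' wholesale or per group when calling [net_charge()] or
#' [isoelectric_point()].
#'
#' @return Named numeric vector with entries \code{n_term}, \code{c_term},
#'   \code{D}, \code{E}, \code{H}, \code{C}, \code{Y}, \code{K}, \code{R}.
#' @export
default_pka <- function() {
  c(n_term = 7.5, c_term = 3.55,
    D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0, R = 12.0)
}

#' Turgencin peptide sequences
#'
#' One-letter sequences of the two cationic antimicrobial peptides from the
#' Arctic sea squirt \emph{Synoicum turgens} used throughout the examples:
#' the full 36-residue turgencin A, its 34-residue Edman read (the N-terminal
#' fragment recovered before the C-terminal dipeptide was located), and the
#' 35-residue turgencin B. Both mature peptides carry six cysteines and are
#' C-terminally amidated.
#'
#' @return Named character vector with elements \code{A}, \code{A34} and
#'   \code{B}.
#' @export
turgencin_sequences <- function() {
  c(A   = "GPKTKAACKMACKLATCGKKPGGWKCKLCELGCDAV",
    A34 = "GPKTKAACKMACKLATCGKKPGGWKCKLCELGCD",
    B   = "GIKEMLCNMACAQTVCKKSGGPLCDTCQAACKALG")
}
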