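# Monoisotopic mass arithmetic for the 2PCA soft-spot workflow.
# All residue masses and workflow constants are derived from the element
# table at load time so there is a single source of truth.

.ELEMENTS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# CODATA proton mass; no electron-mass correction is applied anywhere
# (m/z convention: neutral mass plus z protons, divided by z).
.PROTON <- 1.00727646688

.RESIDUE_FORMULAS <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic element masses
#'
#' @return Named numeric vector of monoisotopic atomic masses (Da) for the
#'   elements used in peptide chemistry (C, H, N, O, S).
#' @export
element_masses <- function() .ELEMENTS

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style elemental formula (e.g. `"C6H3N"`) and returns the sum
#' of monoisotopic atomic masses. No electron-mass correction is applied.
#'
#' @param formula Character scalar, e.g. `"H2O"`, `"C6H7N2"`. The empty
#'   string has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")    # 18.0106
#' formula_mass("C6H3N")  # 89.0265, the 2PCA imidazolidinone residual
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) return(0)
  parts <- regmatches(formula,
                      gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("malformed elemental formula: '", formula, "'")
  }
  sym <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  cnt[is.na(cnt)] <- 1
  unknown <- setdiff(sym, names(.ELEMENTS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ELEMENTS[sym] * cnt)
}

.RESIDUES <- vapply(.RESIDUE_FORMULAS, formula_mass, numeric(1))

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of residue (dehydrated amino-acid)
#'   monoisotopic masses for the 20 standard amino acids, computed from
#'   their elemental formulas. Cys is unmodified.
#' @export
residue_masses <- function() .RESIDUES

#' Chemical constants of the 2PCA workflow
#'
#' All values derive from the element table:
#' \describe{
#'   \item{WATER}{mass(H2O), the ring-opening hydrolysis shift (18.0106 Da).}
#'   \item{CO}{mass(CO), the spacing of the diagnostic a1/b1-type doublet
#'     (27.9949 Da).}
#'   \item{PROTON}{charge carrier mass.}
#'   \item{H_ATOM}{mass of a hydrogen atom, the hydrogen-transfer offset
#'     (1.0078 Da).}
#'   \item{PCA_RESIDUAL}{mass(C6H3N), the residual mass the imidazolidinone
#'     adds to the peptide (89.0265 Da).}
#'   \item{DIAG_ION_MZ}{mass(C6H7N2), the conjugation-specific marker ion
#'     m/z 107.0609; the printed formula already includes the charging
#'     proton.}
#' }
#' @return Named list of masses (Da).
#' @export
pca_constants <- function() .CONSTANTS

.CONSTANTS <- list(
  WATER        = formula_mass("H2O"),
  CO           = formula_mass("CO"),
  PROTON       = .PROTON,
  H_ATOM       = .ELEMENTS[["H"]],
  PCA_RESIDUAL = formula_mass("C6H3N"),
  DIAG_ION_MZ  = formula_mass("C6H7N2")
)

.residue_mass <- function(code, pos = NULL) {
  m <- .RESIDUES[code]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    where <- if (is.null(pos)) bad else pos[bad]
    stop("unknown residue '", code[bad], "' at position ", where)
  }
  unname(m)
}

.split_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Monoisotopic peptide mass
#'
#' @param sequence One-letter residue string.
#' @param topology `"linear"` (sum of residues plus water) or `"cyclic"`
#'   (head-to-tail macrocycle: bare residue sum).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                    # glycine, 75.0320
#' peptide_mass("CYAAPLKPAKSC", "cyclic")
#' @export
peptide_mass <- function(sequence, topology = c("linear", "cyclic")) {
  topology <- match.arg(topology)
  res <- .split_residues(sequence)
  if (!length(res)) stop("empty sequence")
  total <- sum(.residue_mass(res, seq_along(res)))
  if (topology == "linear") total + .CONSTANTS$WATER else total
}

#' m/z of a protonated species
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return `(neutral_mass + charge * PROTON) / charge`.
#' @export
mz <- function(neutral_mass, charge = 1L) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * .PROTON) / charge
}

# symmetric ppm window membership, computed on the target m/z
.within_ppm <- function(observed, target, ppm) {
  abs(observed - target) <= target * ppm * 1e-6
}
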