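## Physical constants (CODATA 2018) and element tables used throughout.

#' Physical constants for mobility calculations
#'
#' CODATA values for the constants entering the Mason-Schamp relation and
#' drift-time kinematics: the elementary charge, the Boltzmann constant, the
#' buffer-gas number density at standard conditions (Loschmidt constant),
#' the proton mass and the unified-atomic-mass-unit/kg conversion.
#'
#' @return Named list with elements \code{e} (C), \code{kb} (J/K), \code{N0}
#'   (m^-3 at 273.15 K and 760 Torr), \code{proton_mass} (u), \code{amu_to_kg}.
#' @examples
#' physicalConstants()$e
#' @export
physicalConstants <- function() {
  list(
    e           = 1.602176634e-19,
    kb          = 1.380649e-23,
    N0          = 2.6867811e25,
    proton_mass = 1.007276466,
    amu_to_kg   = 1.66053906660e-27
  )
}

## 13C - 12C mass difference: lattice spacing of coarse-grained isotope
## patterns (protein +k peaks are 13C-dominated).
.NEUTRON_SPACING <- 1.0033548378

## Isotope abundance vectors per element, indexed by neutron-count shift
## from the lightest isotope (IUPAC 2021), plus monoisotopic and average
## atomic masses. Order of vector entries: +0, +1, +2, ... neutrons.
.ELEMENTS <- list(
  C = list(mono = 12.0,           avg = 12.011,  ab = c(0.9893, 0.0107)),
  H = list(mono = 1.00782503207,  avg = 1.008,   ab = c(0.999885, 0.000115)),
  N = list(mono = 14.0030740048,  avg = 14.007,  ab = c(0.99636, 0.00364)),
  O = list(mono = 15.9949146196,  avg = 15.999,  ab = c(0.99757, 0.00038, 0.00205)),
  S = list(mono = 31.97207100,    avg = 32.06,   ab = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
)

## Amino-acid residue formulas (residue = amino acid minus water),
## element order C, H, N, O, S.
.RESIDUES <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

## Bondi van der Waals radii (Angstrom) for projection-approximation CCS.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.VDW_DEFAULT <- 1.70

## Approximate atomic masses for structure models (u).
.ATOM_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, Zn = 65.38, Fe = 55.845)

#' Mass of an elemental formula
#'
#' @param formula Named integer vector of element counts (names from
#'   C, H, N, O, S).
#' @param kind \code{"average"} or \code{"monoisotopic"}.
#' @return Mass in u.
#' @examples
#' formulaMass(c(C = 1, H = 4), "average")
#' @export
formulaMass <- function(formula, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  els <- names(formula)
  bad <- setdiff(els, names(.ELEMENTS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  m <- vapply(els, function(e)
    if (kind == "average") .ELEMENTS[[e]]$avg else .ELEMENTS[[e]]$mono,
    numeric(1))
  sum(m * as.numeric(formula))
}
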