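## de la Mora Rayleigh-limit screen: separates native-like conformer
## spreads from candidates for coulombically driven gas-phase unfolding.

#' Rayleigh charge limit of a protein or oligomer
#'
#' Empirical maximum number of charges a compact (native-fold) protein ion
#' of mass M_R can carry: z_R = 0.0778 sqrt(M_R), M_R in u. Observed charges
#' above z_R suggest coulombically driven unfolding rather than solution
#' structure.
#'
#' @param massU mass in u
#' @param constant the empirical prefactor (exposed for sensitivity checks)
#' @return Real-valued limit z_R.
#' @examples
#' rayleighLimit(5733.55)  # ~5.89: a 6+ insulin monomer exceeds its limit
#' @export
rayleighLimit <- function(massU, constant = 0.0778) {
  if (any(massU <= 0)) stop("mass must be positive")
  constant * sqrt(massU)
}

#' Screen a species list against the Rayleigh limit
#'
#' @param species list of \linkS4class{IonSpecies}
#' @param constant empirical prefactor of \code{\link{rayleighLimit}}
#' @return data.frame with columns label, M_R (u), z_obs, z_R, exceeds.
#' @examples
#' flagSpecies(list(ionSpecies(1, 6), ionSpecies(2, 7)))
#' @export
flagSpecies <- function(species, constant = 0.0778) {
  if (!length(species)) stop("empty species list")
  rows <- lapply(species, function(s) {
    M <- s@n * s@monomerMassAvg
    zR <- rayleighLimit(M, constant)
    data.frame(label = s@label, M_R = M, z_obs = s@z, z_R = zR,
               exceeds = s@z > zR)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
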