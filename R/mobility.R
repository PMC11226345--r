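## Mobility physics kernel: Mason-Schamp conversion, reduced-mobility
## normalisation and the arrival-time vs P/V regression.

#' Reduced mass of an ion/buffer-gas pair
#'
#' @param ionMass ion mass in u
#' @param gasMass buffer-gas mass in u
#' @return Reduced mass m1*m2/(m1+m2) in u.
#' @examples
#' reducedMass(5733.55, 4.002602)
#' @export
reducedMass <- function(ionMass, gasMass) {
  if (any(ionMass <= 0) || any(gasMass <= 0))
    stop("masses must be positive")
  ionMass * gasMass / (ionMass + gasMass)
}

#' Collision cross section from reduced mobility (Mason-Schamp)
#'
#' Low-field Mason-Schamp relation: the momentum-transfer collision integral
#' Omega = (3 z e)/(16 N0) * sqrt(2 pi / (mu kb T)) / K0, with the reduced
#' mass mu converted to kg and K0 to SI, reported in Angstrom^2.
#'
#' @param K0 reduced mobility in cm^2 V^-1 s^-1
#' @param z charge count
#' @param temperature effective temperature in K
#' @param mu reduced mass in u
#' @return CCS in Angstrom^2.
#' @examples
#' ccsFromReducedMobility(1.0, 1, 300, 4.0)  # ~534.3
#' @export
ccsFromReducedMobility <- function(K0, z, temperature, mu) {
  if (any(c(K0, z, temperature, mu) <= 0))
    stop("all arguments must be positive")
  cst <- physicalConstants()
  muKg <- mu * cst$amu_to_kg
  omega <- (3 * z * cst$e) / (16 * cst$N0) *
    sqrt(2 * pi / (muKg * cst$kb * temperature)) / (K0 * 1e-4)
  omega * 1e20
}

#' Reduced mobility from collision cross section
#'
#' Exact algebraic inverse of \code{\link{ccsFromReducedMobility}}.
#'
#' @param ccs CCS in Angstrom^2
#' @param z charge count
#' @param temperature K
#' @param mu reduced mass in u
#' @return K0 in cm^2 V^-1 s^-1.
#' @export
reducedMobilityFromCcs <- function(ccs, z, temperature, mu) {
  if (any(c(ccs, z, temperature, mu) <= 0))
    stop("all arguments must be positive")
  cst <- physicalConstants()
  muKg <- mu * cst$amu_to_kg
  K0si <- (3 * z * cst$e) / (16 * cst$N0) *
    sqrt(2 * pi / (muKg * cst$kb * temperature)) / (ccs * 1e-20)
  K0si * 1e4
}

#' Normalise a mobility to standard conditions
#'
#' @param K mobility in cm^2 V^-1 s^-1 measured at P, T
#' @param pressure Torr
#' @param temperature K
#' @return Reduced mobility K0 = K * (P/760) * (273.15/T).
#' @examples
#' normalizeMobility(119.2, 3.5, 300)  # ~0.5
#' @export
normalizeMobility <- function(K, pressure, temperature) {
  if (pressure <= 0 || temperature <= 0) stop("P and T must be positive")
  K * (pressure / 760) * (273.15 / temperature)
}

#' Dead time for a given m/z
#'
#' @param instrument an \linkS4class{InstrumentConfig}
#' @param mz nominal m/z
#' @return Dead time in ms (\code{deadTimeCoeff * sqrt(mz)} microseconds).
#' @export
instrumentDeadTime <- function(instrument, mz) {
  instrument@deadTimeCoeff * sqrt(mz) / 1000
}

#' Predict the arrival time of an ion
#'
#' Arrival time = dead time (m/z-dependent, voltage-invariant) + drift time
#' L^2 (P/760) (273.15/T) / (K0 V).
#'
#' @param K0 reduced mobility in cm^2 V^-1 s^-1
#' @param instrument an \linkS4class{InstrumentConfig}
#' @param V drift voltage in volts
#' @param mz nominal m/z (sets the dead time)
#' @return Arrival time in ms.
#' @examples
#' predictArrivalTime(0.5, instrumentConfig(), 40, 1639.2)
#' @export
predictArrivalTime <- function(K0, instrument, V, mz) {
  if (any(V <= 0)) stop("V must be positive")
  tdrift <- 1000 * instrument@driftLength^2 *
    (instrument@pressure / 760) * (273.15 / instrument@temperature) /
    (K0 * V)
  instrumentDeadTime(instrument, mz) + tdrift
}

#' Regress arrival time on P/V to obtain dead time and reduced mobility
#'
#' Ordinary least squares of arrival time (ms) on P/V (Torr/volt). The
#' intercept is the dead time; the slope carries 1/K and, folded with the
#' cell length and the P,T normalisation, yields the reduced mobility
#' directly: slope = 1000 L^2 273.15 / (760 T K0). The K0 standard error is
#' propagated from the slope standard error.
#'
#' @param points data.frame with columns \code{P} (Torr), \code{V} (volts),
#'   \code{t} (ms)
#' @param instrument an \linkS4class{InstrumentConfig} supplying L and T
#' @param weights optional OLS weights (default unweighted)
#' @return A \linkS4class{MobilityFit}.
#' @examples
#' ins <- instrumentConfig()
#' pts <- data.frame(P = 3.5, V = ins@voltages,
#'                   t = predictArrivalTime(0.5, ins, ins@voltages, 1639))
#' mobilityRegression(pts, ins)
#' @export
mobilityRegression <- function(points, instrument, weights = NULL) {
  stopifnot(all(c("P", "V", "t") %in% names(points)))
  x <- points$P / points$V
  if (length(unique(signif(x, 12))) < 2L)
    stop("need >= 2 points with distinct P/V")
  fit <- if (is.null(weights)) stats::lm(points$t ~ x)
         else stats::lm(points$t ~ x, weights = weights)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  if (slope <= 0) stop("non-physical mobility: fitted slope is not positive")
  sm <- suppressWarnings(summary(fit))  # noise-free data fit exactly
  se <- tryCatch(sm$coefficients[2, 2], error = function(e) NA_real_)
  if (!is.finite(se)) se <- 0
  r2 <- if (length(x) == 2L) 1 else sm$r.squared
  K0 <- 1000 * instrument@driftLength^2 * 273.15 /
    (760 * instrument@temperature * slope)
  new("MobilityFit", slope = slope, intercept = intercept,
      rSquared = min(r2, 1), K0 = K0, K0Stderr = K0 * se / slope,
      nPoints = length(x))
}
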