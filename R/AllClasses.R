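#' @import methods
NULL

## ---------------------------------------------------------------------------
## InstrumentConfig
## ---------------------------------------------------------------------------

#' Drift-tube instrument configuration
#'
#' Geometry and operating conditions of a linear drift cell: drift length,
#' helium pressure, temperature, the set of drift voltages stepped during a
#' mobility experiment, and the parameters of the synthetic-instrument model
#' (dead-time coefficient, peak-width inflation, time-axis binning).
#'
#' The dead time — the interval an ion spends outside the drift cell — is
#' modelled as \code{dead_time_coeff * sqrt(m/z)} microseconds: it depends on
#' m/z (time-of-flight optics) but not on drift voltage.
#'
#' @slot driftLength drift-cell length in cm
#' @slot pressure buffer-gas pressure in Torr
#' @slot temperature cell temperature in K
#' @slot bufferGasMass buffer-gas mass in u (helium by default)
#' @slot voltages drift voltages in V (at least two, distinct)
#' @slot deadTimeCoeff dead-time coefficient, microseconds per sqrt(m/z)
#' @slot widthInflation multiplier (>= 1) on the diffusion-limited peak width
#' @slot binWidth time-axis bin width in microseconds
#' @export
setClass("InstrumentConfig",
  representation(
    driftLength   = "numeric",
    pressure      = "numeric",
    temperature   = "numeric",
    bufferGasMass = "numeric",
    voltages      = "numeric",
    deadTimeCoeff = "numeric",
    widthInflation = "numeric",
    binWidth      = "numeric"
  )
)

setValidity("InstrumentConfig", function(object) {
  msg <- character(0)
  if (object@driftLength <= 0) msg <- c(msg, "driftLength must be > 0")
  if (object@pressure <= 0) msg <- c(msg, "pressure must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (object@bufferGasMass <= 0) msg <- c(msg, "bufferGasMass must be > 0")
  if (length(object@voltages) < 2) msg <- c(msg, "need at least 2 voltages")
  if (any(object@voltages <= 0)) msg <- c(msg, "voltages must be > 0")
  if (anyDuplicated(object@voltages)) msg <- c(msg, "voltages must be distinct")
  if (object@widthInflation < 1) msg <- c(msg, "widthInflation must be >= 1")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an InstrumentConfig
#'
#' Defaults reproduce the study conditions: a 5.1 cm drift cell filled with
#' helium at 3.5 Torr, 300 K, and six drift voltages spanning 25-60 V.
#'
#' @param driftLength cm
#' @param pressure Torr
#' @param temperature K
#' @param bufferGasMass u
#' @param voltages V
#' @param deadTimeCoeff microseconds per sqrt(m/z)
#' @param widthInflation dimensionless, >= 1
#' @param binWidth microseconds
#' @return An \linkS4class{InstrumentConfig}.
#' @examples
#' instrumentConfig()
#' @export
instrumentConfig <- function(driftLength = 5.1, pressure = 3.5,
                             temperature = 300, bufferGasMass = 4.002602,
                             voltages = c(25, 32, 39, 46, 53, 60),
                             deadTimeCoeff = 2.0, widthInflation = 1.0,
                             binWidth = 2.0) {
  new("InstrumentConfig", driftLength = driftLength, pressure = pressure,
      temperature = temperature, bufferGasMass = bufferGasMass,
      voltages = voltages, deadTimeCoeff = deadTimeCoeff,
      widthInflation = widthInflation, binWidth = binWidth)
}

setMethod("show", "InstrumentConfig", function(object) {
  cat("InstrumentConfig: L =", object@driftLength, "cm, P =",
      object@pressure, "Torr, T =", object@temperature, "K\n")
  cat("  voltages (V):", paste(object@voltages, collapse = ", "), "\n")
  cat("  dead-time coeff:", object@deadTimeCoeff,
      "us/sqrt(m/z); bin:", object@binWidth, "us\n")
})

## ---------------------------------------------------------------------------
## IonSpecies
## ---------------------------------------------------------------------------

#' An oligomeric ion [nM + zH]^z+
#'
#' One protonated oligomer of a protein: the monomer elemental formula, the
#' oligomer order n, the charge z, and derived masses and m/z under both the
#' average and monoisotopic mass conventions.
#'
#' @slot label text label, e.g. "[2M+7H]7+"
#' @slot n oligomer order (monomer count)
#' @slot z protonation / charge count
#' @slot formula monomer element counts (named integer vector)
#' @slot monomerMassAvg average monomer mass in u
#' @slot monomerMassMono monoisotopic monomer mass in u
#' @slot mzAvg average-mass m/z
#' @slot mzMono monoisotopic m/z
#' @export
setClass("IonSpecies",
  representation(
    label = "character", n = "integer", z = "integer",
    formula = "numeric",
    monomerMassAvg = "numeric", monomerMassMono = "numeric",
    mzAvg = "numeric", mzMono = "numeric"
  )
)

setValidity("IonSpecies", function(object) {
  msg <- character(0)
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@z < 1L) msg <- c(msg, "z must be >= 1")
  if (any(object@formula < 0)) msg <- c(msg, "formula counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an IonSpecies
#'
#' @param n oligomer order
#' @param z charge
#' @param formula monomer elemental formula (named counts); default is the
#'   bovine insulin monomer with intact disulfides
#' @param label optional label; default "[nM+zH]z+"
#' @return An \linkS4class{IonSpecies}.
#' @examples
#' ionSpecies(2, 7)
#' @export
ionSpecies <- function(n, z, formula = insulinFormula(), label = NULL) {
  n <- as.integer(n); z <- as.integer(z)
  if (is.null(label))
    label <- sprintf("[%sM+%dH]%d+", if (n == 1L) "" else n, z, z)
  pm <- physicalConstants()$proton_mass
  mAvg <- formulaMass(formula, "average")
  mMono <- formulaMass(formula, "monoisotopic")
  new("IonSpecies", label = label, n = n, z = z, formula = formula,
      monomerMassAvg = mAvg, monomerMassMono = mMono,
      mzAvg = (n * mAvg + z * pm) / z, mzMono = (n * mMono + z * pm) / z)
}

setMethod("show", "IonSpecies", function(object) {
  cat(sprintf("IonSpecies %s: n=%d z=%d, avg m/z %.3f (mono %.3f)\n",
              object@label, object@n, object@z, object@mzAvg, object@mzMono))
})

## ---------------------------------------------------------------------------
## NoiseModel / GroundTruth
## ---------------------------------------------------------------------------

#' Counting-noise model for the synthetic instrument
#'
#' @slot peakCounts expected counts at the tallest peak bin (0 = noise-free
#'   exact profile)
#' @slot baselineCounts mean baseline counts per bin
#' @slot seed integer seed recorded in the bundle manifest
#' @export
setClass("NoiseModel",
  representation(peakCounts = "numeric", baselineCounts = "numeric",
                 seed = "integer"))

setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (object@peakCounts < 0) msg <- c(msg, "peakCounts must be >= 0")
  if (object@baselineCounts < 0) msg <- c(msg, "baselineCounts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param peakCounts expected counts at the tallest peak (0 for noise-free)
#' @param baselineCounts mean baseline counts per bin
#' @param seed integer seed
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(peakCounts = 0, baselineCounts = 0, seed = 1L) {
  new("NoiseModel", peakCounts = peakCounts, baselineCounts = baselineCounts,
      seed = as.integer(seed))
}

#' Ground truth for a synthetic ATD bundle
#'
#' The m/z-coincident species contributing to one selected-ion arrival time
#' distribution, each with 1-4 conformer families (CCS in Angstrom^2 and
#' relative abundances summing to 1 within a species), relative weights
#' between species, and a noise model.
#'
#' @slot species list of \linkS4class{IonSpecies}
#' @slot families list (parallel to species) of data.frames with columns
#'   \code{ccs}, \code{abundance}
#' @slot speciesWeights relative weight of each species in the composite ATD
#' @slot noise a \linkS4class{NoiseModel}
#' @export
setClass("GroundTruth",
  representation(species = "list", families = "list",
                 speciesWeights = "numeric", noise = "NoiseModel"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (!length(object@species)) msg <- c(msg, "species list must be non-empty")
  if (length(object@families) != length(object@species))
    msg <- c(msg, "families must parallel species")
  for (fam in object@families) {
    if (!is.data.frame(fam) || !all(c("ccs", "abundance") %in% names(fam)))
      msg <- c(msg, "each families entry needs columns ccs, abundance")
    else {
      if (nrow(fam) < 1L || nrow(fam) > 4L)
        msg <- c(msg, "1-4 conformer families per species")
      if (any(fam$abundance < 0) || abs(sum(fam$abundance) - 1) > 1e-9)
        msg <- c(msg, "abundances must be >= 0 and sum to 1 within a species")
      if (any(fam$ccs <= 0)) msg <- c(msg, "family CCS must be > 0")
    }
  }
  if (length(object@speciesWeights) != length(object@species) ||
      any(object@speciesWeights < 0) || sum(object@speciesWeights) <= 0)
    msg <- c(msg, "speciesWeights must be non-negative with positive sum")
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a GroundTruth
#'
#' @param species an \linkS4class{IonSpecies} or list of them
#' @param families data.frame (ccs, abundance) or list of such, parallel to
#'   \code{species}
#' @param speciesWeights relative weights between species (default equal)
#' @param noise a \linkS4class{NoiseModel}
#' @return A \linkS4class{GroundTruth}.
#' @examples
#' groundTruth(ionSpecies(2, 7),
#'             data.frame(ccs = c(1217, 1324), abundance = c(0.7, 0.3)))
#' @export
groundTruth <- function(species, families, speciesWeights = NULL,
                        noise = noiseModel()) {
  if (is(species, "IonSpecies")) species <- list(species)
  if (is.data.frame(families)) families <- list(families)
  if (!length(species)) stop("empty species list")
  if (is.null(speciesWeights))
    speciesWeights <- rep(1 / length(species), length(species))
  new("GroundTruth", species = species, families = families,
      speciesWeights = speciesWeights / sum(speciesWeights), noise = noise)
}

## ---------------------------------------------------------------------------
## ATDSet
## ---------------------------------------------------------------------------

#' A multi-voltage set of arrival time distributions
#'
#' One trace (time/intensity histogram) per drift voltage for a single
#' nominal m/z, with the instrument configuration and, for synthetic bundles,
#' a manifest embedding the ground truth.
#'
#' @slot traces list; each element a list with fields \code{P} (Torr),
#'   \code{V} (volts), \code{time_ms}, \code{intensity}
#' @slot mz nominal m/z of the selected ion
#' @slot instrument the \linkS4class{InstrumentConfig}
#' @slot manifest list of provenance metadata (ground truth, seed)
#' @export
setClass("ATDSet",
  representation(traces = "list", mz = "numeric",
                 instrument = "InstrumentConfig", manifest = "list"))

setValidity("ATDSet", function(object) {
  msg <- character(0)
  if (length(object@traces) < 2L) msg <- c(msg, "need >= 2 traces")
  for (tr in object@traces) {
    if (!all(c("P", "V", "time_ms", "intensity") %in% names(tr)))
      msg <- c(msg, "trace fields: P, V, time_ms, intensity")
    else if (is.unsorted(tr$time_ms, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing within a trace")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @rdname ATDSet-class
#' @param object an ATDSet
#' @export
setMethod("show", "ATDSet", function(object) {
  vs <- vapply(object@traces, function(tr) tr$V, numeric(1))
  cat(sprintf("ATDSet at m/z %.2f: %d traces, V = %s\n", object@mz,
              length(object@traces), paste(vs, collapse = ", ")))
})

#' Voltages of an ATDSet
#' @param x an \linkS4class{ATDSet}
#' @return Numeric vector of drift voltages.
#' @export
atdVoltages <- function(x) vapply(x@traces, function(tr) tr$V, numeric(1))

#' Traces of an ATDSet
#' @param x an \linkS4class{ATDSet}
#' @return List of per-voltage traces.
#' @export
atdTraces <- function(x) x@traces

## ---------------------------------------------------------------------------
## MobilityFit
## ---------------------------------------------------------------------------

#' Arrival-time vs P/V regression result
#'
#' Ordinary least squares of arrival time on pressure/voltage: the intercept
#' is the (voltage-invariant) dead time and the slope carries 1/K, from which
#' the reduced mobility K0 is extracted.
#'
#' @slot slope ms per (Torr/V)
#' @slot intercept dead time in ms
#' @slot rSquared coefficient of determination
#' @slot K0 reduced mobility, cm^2 V^-1 s^-1
#' @slot K0Stderr standard error of K0 (propagated from the slope)
#' @slot nPoints number of (P, V, t) points
#' @export
setClass("MobilityFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", K0 = "numeric", K0Stderr = "numeric",
                 nPoints = "integer"))

setValidity("MobilityFit", function(object) {
  msg <- character(0)
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (object@K0 <= 0) msg <- c(msg, "K0 must be > 0")
  if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MobilityFit", function(object) {
  cat(sprintf(
    "MobilityFit: K0 = %.4f +/- %.4g cm2/V/s, dead time %.4f ms, R2 = %.6f (n = %d)\n",
    object@K0, object@K0Stderr, object@intercept, object@rSquared,
    object@nPoints))
})

#' Reduced mobility of a fit
#' @param x a \linkS4class{MobilityFit}
#' @return K0 in cm^2 V^-1 s^-1.
#' @export
reducedMobility <- function(x) x@K0

#' Dead time of a fit
#' @param x a \linkS4class{MobilityFit}
#' @return Dead time in ms.
#' @export
deadTime <- function(x) x@intercept

## ---------------------------------------------------------------------------
## ConformerFamily
## ---------------------------------------------------------------------------

#' One resolved conformer family
#'
#' A single arrival-time component tracked across drift voltages, with its
#' collision cross section (from the per-family mobility regression), the
#' propagated uncertainty, and its relative abundance within the species.
#' Rank 1 is the earliest-arriving (most compact) family.
#'
#' @slot ccs Angstrom^2
#' @slot ccsStderr Angstrom^2
#' @slot abundance fraction of the species total
#' @slot rank 1 = earliest-arriving
#' @slot perVoltageCentroids data.frame with columns V, t, sigma, area
#' @slot fit the underlying \linkS4class{MobilityFit} (or empty list)
#' @export
setClass("ConformerFamily",
  representation(ccs = "numeric", ccsStderr = "numeric",
                 abundance = "numeric", rank = "integer",
                 perVoltageCentroids = "data.frame", fit = "ANY"))

setValidity("ConformerFamily", function(object) {
  msg <- character(0)
  if (length(object@ccs) && object@ccs <= 0) msg <- c(msg, "ccs must be > 0")
  if (length(object@abundance) &&
      (object@abundance < -1e-12 || object@abundance > 1 + 1e-12))
    msg <- c(msg, "abundance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConformerFamily", function(object) {
  cat(sprintf("ConformerFamily rank %d: CCS %.1f +/- %.2f A2, abundance %.3f\n",
              object@rank, object@ccs, object@ccsStderr, object@abundance))
})

#' Collision cross section accessor
#' @param x a \linkS4class{ConformerFamily}
#' @return CCS in Angstrom^2.
#' @export
ccs <- function(x) x@ccs

#' Abundance accessor
#' @param x a \linkS4class{ConformerFamily}
#' @return Fractional abundance within the species.
#' @export
abundance <- function(x) x@abundance

## ---------------------------------------------------------------------------
## IsotopePattern
## ---------------------------------------------------------------------------

#' Isotopologue stick pattern at a given charge
#'
#' @slot sticks data.frame with columns \code{mz} and \code{abundance}
#'   (normalised to max 1)
#' @slot charge z
#' @slot spacing adjacent stick spacing in m/z units (1.0033548378 / z)
#' @export
setClass("IsotopePattern",
  representation(sticks = "data.frame", charge = "integer",
                 spacing = "numeric"))

setValidity("IsotopePattern", function(object) {
  msg <- character(0)
  st <- object@sticks
  if (!all(c("mz", "abundance") %in% names(st)))
    msg <- c(msg, "sticks needs columns mz, abundance")
  else {
    if (abs(max(st$abundance) - 1) > 1e-9)
      msg <- c(msg, "abundances must be normalised to max 1")
    if (nrow(st) > 1 &&
        any(abs(diff(st$mz) - object@spacing) > 1e-6))
      msg <- c(msg, "adjacent stick spacing must equal spacing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "IsotopePattern", function(object) {
  cat(sprintf("IsotopePattern: %d sticks at z=%d, spacing %.6f m/z\n",
              nrow(object@sticks), object@charge, object@spacing))
})

## ---------------------------------------------------------------------------
## StructureModel
## ---------------------------------------------------------------------------

#' An atomic structure for structure-side metrics
#'
#' @slot element character vector of element symbols
#' @slot mass atomic masses in u
#' @slot xyz numeric matrix (n x 3), Angstrom
#' @slot radius van der Waals radii in Angstrom
#' @slot label text label
#' @export
setClass("StructureModel",
  representation(element = "character", mass = "numeric", xyz = "matrix",
                 radius = "numeric", label = "character"))

setValidity("StructureModel", function(object) {
  msg <- character(0)
  n <- nrow(object@xyz)
  if (n < 1L) msg <- c(msg, "need >= 1 atom")
  if (ncol(object@xyz) != 3L) msg <- c(msg, "xyz must be n x 3")
  if (length(object@mass) != n || length(object@radius) != n ||
      length(object@element) != n)
    msg <- c(msg, "element, mass, radius must parallel xyz rows")
  if (any(object@mass <= 0)) msg <- c(msg, "masses must be > 0")
  if (any(object@radius <= 0)) msg <- c(msg, "radii must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureModel
#'
#' @param xyz n x 3 coordinate matrix (Angstrom)
#' @param element element symbols (recycled); used to look up masses and
#'   Bondi radii when \code{mass}/\code{radius} are not given
#' @param mass atomic masses in u (optional)
#' @param radius van der Waals radii in Angstrom (optional)
#' @param label text label
#' @return A \linkS4class{StructureModel}.
#' @examples
#' structureModel(rbind(c(0, 0, 0), c(2, 0, 0)), element = "C")
#' @export
structureModel <- function(xyz, element = "C", mass = NULL, radius = NULL,
                           label = "structure") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  element <- rep_len(element, n)
  if (is.null(mass)) {
    mass <- unname(.ATOM_MASSES[element])
    mass[is.na(mass)] <- 12.011
  }
  if (is.null(radius)) {
    radius <- unname(.VDW_RADII[element])
    radius[is.na(radius)] <- .VDW_DEFAULT
  }
  new("StructureModel", element = element, mass = rep_len(mass, n),
      xyz = xyz, radius = rep_len(radius, n), label = label)
}

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel '%s': %d atoms\n", object@label,
              nrow(object@xyz)))
})
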