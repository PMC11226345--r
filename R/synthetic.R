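## Synthetic drift-tube instrument: ground-truth-labelled ATD bundles,
## high-resolution isotope spectra and CID stick spectra.

## Diffusion-limited single-peak resolving power t/dt(FWHM) at drift
## voltage V for charge z: sqrt(z e V / (16 ln2 kb T)).
.diffusionResolvingPower <- function(z, V, temperature) {
  cst <- physicalConstants()
  sqrt(z * cst$e * V / (16 * log(2) * cst$kb * temperature))
}

## Per-family Gaussian parameters at one voltage.
.familyPeak <- function(ccsVal, z, ionMass, instrument, V, mz) {
  mu <- reducedMass(ionMass, instrument@bufferGasMass)
  K0 <- reducedMobilityFromCcs(ccsVal, z, instrument@temperature, mu)
  tdead <- instrumentDeadTime(instrument, mz)
  t <- predictArrivalTime(K0, instrument, V, mz)
  rp <- .diffusionResolvingPower(z, V, instrument@temperature)
  sigma <- (t - tdead) / rp / 2.3548200450309493 * instrument@widthInflation
  list(center = t, sigma = sigma)
}

#' Simulate a multi-voltage ATD bundle
#'
#' For every drift voltage in the instrument configuration, builds an
#' arrival-time trace in which each conformer family of each (possibly
#' m/z-coincident) species contributes a Gaussian centred at
#' dead time + drift time, with the diffusion-limited peak width and area
#' proportional to its ground-truth abundance. With \code{peakCounts > 0}
#' the profile is scaled so the tallest bin has that expected count and
#' Poisson counting noise (plus any baseline) is drawn; otherwise the exact
#' profile is returned. The ground truth is embedded in the manifest.
#'
#' @param truth a \linkS4class{GroundTruth}
#' @param instrument an \linkS4class{InstrumentConfig}
#' @return An \linkS4class{ATDSet}.
#' @examples
#' tr <- groundTruth(ionSpecies(2, 7),
#'                   data.frame(ccs = c(1217, 1324), abundance = c(0.7, 0.3)))
#' simulateATDSet(tr, instrumentConfig())
#' @export
simulateATDSet <- function(truth, instrument) {
  validObject(truth); validObject(instrument)
  species <- truth@species
  if (!length(species)) stop("empty species list")
  mz <- species[[1]]@mzAvg
  binMs <- instrument@binWidth / 1000

  ## collect all peaks across voltages to lay out the grid and check widths
  peaks <- list()
  for (vi in seq_along(instrument@voltages)) {
    V <- instrument@voltages[vi]
    for (si in seq_along(species)) {
      sp <- species[[si]]
      fam <- truth@families[[si]]
      ionMass <- sp@n * sp@monomerMassAvg +
        sp@z * physicalConstants()$proton_mass
      for (fi in seq_len(nrow(fam))) {
        pk <- .familyPeak(fam$ccs[fi], sp@z, ionMass, instrument, V, mz)
        peaks[[length(peaks) + 1L]] <- c(vi = vi, center = pk$center,
          sigma = pk$sigma,
          area = truth@speciesWeights[si] * fam$abundance[fi])
      }
    }
  }
  pk <- do.call(rbind, peaks)
  if (instrument@binWidth / 1000 > min(pk[, "sigma"]) / 2)
    stop(sprintf(
      paste0("bin underflow: bin width %.1f us exceeds half the narrowest ",
             "peak sigma (%.1f us); reduce binWidth"),
      instrument@binWidth, 1000 * min(pk[, "sigma"])))

  tmax <- max(pk[, "center"] + 8 * pk[, "sigma"])
  times <- seq(binMs / 2, tmax + binMs, by = binMs)

  noise <- truth@noise
  if (noise@peakCounts > 0 || noise@baselineCounts > 0)
    set.seed(noise@seed)

  traces <- vector("list", length(instrument@voltages))
  for (vi in seq_along(instrument@voltages)) {
    rows <- pk[pk[, "vi"] == vi, , drop = FALSE]
    y <- numeric(length(times))
    for (r in seq_len(nrow(rows)))
      y <- y + rows[r, "area"] *
        stats::dnorm(times, rows[r, "center"], rows[r, "sigma"]) * binMs
    if (noise@peakCounts > 0) {
      y <- stats::rpois(length(y), y * noise@peakCounts / max(y))
    }
    if (noise@baselineCounts > 0)
      y <- y + stats::rpois(length(y), noise@baselineCounts)
    traces[[vi]] <- list(P = instrument@pressure,
                         V = instrument@voltages[vi],
                         time_ms = times, intensity = y)
  }

  manifest <- list(
    species = lapply(species, function(s)
      list(label = s@label, n = s@n, z = s@z, mz_avg = s@mzAvg)),
    families = lapply(truth@families, function(f)
      list(ccs = f$ccs, abundance = f$abundance)),
    species_weights = truth@speciesWeights,
    instrument = list(drift_length_cm = instrument@driftLength,
                      pressure_torr = instrument@pressure,
                      temperature_K = instrument@temperature,
                      buffer_gas_mass_u = instrument@bufferGasMass,
                      voltages_V = instrument@voltages,
                      dead_time_coeff_us = instrument@deadTimeCoeff,
                      width_inflation = instrument@widthInflation,
                      bin_width_us = instrument@binWidth),
    noise = list(peak_counts = noise@peakCounts,
                 baseline_counts = noise@baselineCounts, seed = noise@seed))
  new("ATDSet", traces = traces, mz = mz, instrument = instrument,
      manifest = manifest)
}

#' Write an ATD bundle to a directory
#'
#' Writes \code{manifest.json} plus one \code{atd_<V>V.csv}
#' (header \code{time_ms,intensity}) per voltage.
#'
#' @param atd an \linkS4class{ATDSet}
#' @param dir output directory (created if needed)
#' @return The directory, invisibly.
#' @export
writeATDSet <- function(atd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(atd@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in atd@traces) {
    f <- file.path(dir, sprintf("atd_%gV.csv", tr$V))
    utils::write.csv(data.frame(time_ms = tr$time_ms,
                                intensity = tr$intensity),
                     f, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an ATD bundle from a directory
#'
#' @param dir directory written by \code{\link{writeATDSet}}
#' @return An \linkS4class{ATDSet}.
#' @export
readATDSet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  ins <- man$instrument
  instrument <- instrumentConfig(
    driftLength = ins$drift_length_cm, pressure = ins$pressure_torr,
    temperature = ins$temperature_K, bufferGasMass = ins$buffer_gas_mass_u,
    voltages = ins$voltages_V, deadTimeCoeff = ins$dead_time_coeff_us,
    widthInflation = ins$width_inflation, binWidth = ins$bin_width_us)
  traces <- lapply(ins$voltages_V, function(V) {
    d <- utils::read.csv(file.path(dir, sprintf("atd_%gV.csv", V)))
    list(P = ins$pressure_torr, V = V, time_ms = d$time_ms,
         intensity = d$intensity)
  })
  mz <- if (is.data.frame(man$species)) man$species$mz_avg[1]
        else man$species[[1]]$mz_avg
  new("ATDSet", traces = traces, mz = mz, instrument = instrument,
      manifest = man)
}

#' Simulate a high-resolution isotope profile of a species mixture
#'
#' Sums Gaussian-broadened isotopologue sticks for each weighted species
#' (FWHM = m/z / resolving power) on a regular m/z grid and normalises the
#' profile to maximum 1. An m/z-coincident monomer/dimer mixture shows the
#' dimer sticks interleaved at half the monomer spacing.
#'
#' @param speciesWeights list of \code{list(species = IonSpecies, weight =)}
#'   entries, or a list of IonSpecies with a separate \code{weights} vector
#' @param weights optional numeric weights paralleling a plain species list
#' @param resolvingPower FWHM resolving power (> 0)
#' @param gridStep m/z grid step; default resolves the finest stick spacing
#' @param abundanceFloor stick pruning floor
#' @return List with \code{profile} (data.frame mz, intensity),
#'   \code{sticks} per species, and \code{tooCoarse} flag set when the grid
#'   cannot resolve the 1/z spacing.
#' @export
simulateIsotopeSpectrum <- function(speciesWeights, weights = NULL,
                                    resolvingPower = 5e4, gridStep = NULL,
                                    abundanceFloor = 1e-3) {
  if (!is.null(weights)) {
    speciesWeights <- Map(function(s, w) list(species = s, weight = w),
                          speciesWeights, weights)
  }
  w <- vapply(speciesWeights, function(e) e$weight, numeric(1))
  if (any(w < 0) || !any(w > 0)) stop("weights must be >= 0 with one > 0")
  if (resolvingPower <= 0) stop("resolvingPower must be > 0")
  pats <- lapply(speciesWeights, function(e)
    isotopePattern(e$species@formula * e$species@n, e$species@z,
                   abundanceFloor))
  minSpacing <- min(vapply(pats, function(p) p@spacing, numeric(1)))
  allMz <- unlist(lapply(pats, function(p) p@sticks$mz))
  sigmaMin <- min(allMz) / resolvingPower / 2.3548
  if (is.null(gridStep)) gridStep <- min(minSpacing, sigmaMin * 2.3548) / 8
  tooCoarse <- gridStep > minSpacing / 2
  if (tooCoarse)
    warning("grid too coarse to resolve the 1/z isotope spacing")
  grid <- seq(min(allMz) - 5 * sigmaMin, max(allMz) + 5 * sigmaMin,
              by = gridStep)
  y <- numeric(length(grid))
  for (i in seq_along(pats)) {
    if (w[i] == 0) next
    y <- y + w[i] * .patternProfile(pats[[i]], grid, resolvingPower)
  }
  y <- y / max(y)
  list(profile = data.frame(mz = grid, intensity = y), sticks = pats,
       tooCoarse = tooCoarse)
}

#' Simulate a CID stick spectrum of a multimer parent
#'
#' Places sticks at the fragment m/z of each weighted binary fission
#' channel, intensity proportional to the channel weight. Fragments whose
#' m/z coincides with the parent's (within 0.01) are flagged
#' indistinguishable. A monomer parent has no fission channels and yields
#' an empty spectrum.
#'
#' @param parent an \linkS4class{IonSpecies}
#' @param channelWeights named numeric vector; names are channel labels as
#'   produced by \code{\link{cidChannels}}, e.g. \code{"(1,3)+(1,4)"}
#' @return data.frame with columns mz, intensity, fragment (label),
#'   indistinguishable.
#' @export
simulateCIDSpectrum <- function(parent, channelWeights = NULL) {
  ch <- cidChannels(parent)
  if (!nrow(ch))
    return(data.frame(mz = numeric(0), intensity = numeric(0),
                      fragment = character(0),
                      indistinguishable = logical(0)))
  if (is.null(channelWeights))
    channelWeights <- stats::setNames(rep(1, nrow(ch)), ch$label)
  bad <- setdiff(names(channelWeights), ch$label)
  if (length(bad))
    stop("weight on unknown channel(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (lab in names(channelWeights)) {
    wgt <- channelWeights[[lab]]
    if (wgt <= 0) next
    r <- ch[ch$label == lab, ]
    rows[[length(rows) + 1L]] <- data.frame(
      mz = c(r$mz1, r$mz2), intensity = wgt,
      fragment = c(sprintf("(%d,%d)", r$n1, r$z1),
                   sprintf("(%d,%d)", r$n2, r$z2)),
      indistinguishable = c(abs(r$mz1 - parent@mzAvg) <= 0.01,
                            abs(r$mz2 - parent@mzAvg) <= 0.01))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}
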