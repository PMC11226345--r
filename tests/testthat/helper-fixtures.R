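# Shared fixtures: the study-condition instrument and ground truths built
# from the packaged insulin sequences.

studyInstrument <- function(...) instrumentConfig(...)

dimerFourFamilyTruth <- function(noise = noiseModel()) {
  groundTruth(
    ionSpecies(2, 7),
    data.frame(ccs = c(1217, 1324, 1563, 1701),
               abundance = c(0.50, 0.25, 0.15, 0.10)),
    noise = noise)
}

ionMassOf <- function(sp) {
  sp@n * sp@monomerMassAvg + sp@z * physicalConstants()$proton_mass
}

# Full simulate -> deconvolve -> track -> regress -> Mason-Schamp round trip.
simRecover <- function(truth, instrument = studyInstrument(), kMax = 4L) {
  atd <- simulateATDSet(truth, instrument)
  sp <- truth@species[[1]]
  suppressWarnings(atdFamilies(atd, z = sp@z, ionMass = ionMassOf(sp),
                               kMax = kMax))
}

# The oligomer charge states reported for this system (monomer to hexamer).
observedSpeciesList <- function() {
  nz <- rbind(c(1, 3), c(1, 4), c(1, 5), c(1, 6),
              c(2, 4), c(2, 5), c(2, 7), c(2, 9),
              c(3, 8), c(3, 10),
              c(4, 9), c(4, 10), c(4, 11),
              c(5, 11), c(5, 12),
              c(6, 13))
  lapply(seq_len(nrow(nz)), function(i) ionSpecies(nz[i, 1], nz[i, 2]))
}
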