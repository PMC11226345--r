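# Synthetic drift-tube instrument: ATD bundles, isotope profiles and CID
# stick spectra with embedded ground truth.

test_that("noise-free single-family traces are unimodal with exact centroids", {
  ins <- studyInstrument()
  sp <- ionSpecies(1, 4)
  truth <- groundTruth(sp, data.frame(ccs = 850, abundance = 1))
  atd <- simulateATDSet(truth, ins)
  expect_length(atdTraces(atd), 6)
  mu <- reducedMass(ionMassOf(sp), ins@bufferGasMass)
  K0 <- reducedMobilityFromCcs(850, sp@z, ins@temperature, mu)
  for (tr in atdTraces(atd)) {
    centroid <- sum(tr$time_ms * tr$intensity) / sum(tr$intensity)
    predicted <- predictArrivalTime(K0, ins, tr$V, sp@mzAvg)
    expect_equal(centroid, predicted, tolerance = 1e-9)
    # unimodal: one sign change of the smoothed derivative
    y <- tr$intensity[tr$intensity > max(tr$intensity) * 1e-12]
    expect_equal(sum(diff(sign(diff(y))) < 0), 1)
  }
})

test_that("component areas reproduce ground-truth abundances (noise-free)", {
  truth <- dimerFourFamilyTruth()
  atd <- simulateATDSet(truth, studyInstrument())
  for (tr in atdTraces(atd)) {
    comp <- deconvolveATD(tr)
    expect_equal(nrow(comp), 4)
    expect_equal(comp$area / sum(comp$area), c(0.50, 0.25, 0.15, 0.10),
                 tolerance = 1e-6)
  }
})

test_that("centroids are linear in P/V with R^2 at machine precision", {
  ins <- studyInstrument()
  truth <- groundTruth(ionSpecies(2, 7), data.frame(ccs = 1324, abundance = 1))
  atd <- simulateATDSet(truth, ins)
  cent <- vapply(atdTraces(atd), function(tr)
    sum(tr$time_ms * tr$intensity) / sum(tr$intensity), numeric(1))
  x <- ins@pressure / atdVoltages(atd)
  r2 <- suppressWarnings(summary(lm(cent ~ x)))$r.squared
  expect_gte(r2, 1 - 1e-12)
})

test_that("Poisson replicates recover the noise-free centroid on average", {
  ins <- studyInstrument()
  sp <- ionSpecies(2, 7)
  nfTruth <- groundTruth(sp, data.frame(ccs = 1217, abundance = 1))
  nf <- simulateATDSet(nfTruth, ins)
  tr0 <- atdTraces(nf)[[1]]
  target <- sum(tr0$time_ms * tr0$intensity) / sum(tr0$intensity)
  cents <- vapply(1:200, function(s) {
    truth <- groundTruth(sp, data.frame(ccs = 1217, abundance = 1),
                         noise = noiseModel(peakCounts = 500, seed = s))
    tr <- atdTraces(simulateATDSet(truth, ins))[[1]]
    sum(tr$time_ms * tr$intensity) / sum(tr$intensity)
  }, numeric(1))
  se <- sd(cents) / sqrt(length(cents))
  expect_lt(abs(mean(cents) - target), 2 * se + 1e-12)
})

test_that("simulation refuses undersampled bins and empty truths", {
  ins <- studyInstrument(binWidth = 40)
  expect_error(simulateATDSet(dimerFourFamilyTruth(), ins), "bin underflow")
  expect_error(groundTruth(list(), list()), "empty species")
})

test_that("ATD bundles round-trip through the directory format", {
  dir <- file.path(tempdir(), "bundle_rt")
  atd <- simulateATDSet(dimerFourFamilyTruth(), studyInstrument())
  writeATDSet(atd, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readATDSet(dir)
  expect_equal(back@mz, atd@mz, tolerance = 1e-9)
  expect_equal(atdVoltages(back), atdVoltages(atd))
  for (i in seq_along(atd@traces))
    expect_equal(back@traces[[i]]$intensity, atd@traces[[i]]$intensity,
                 tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("isotope profile maxima sit on stick positions and patterns are charge-invariant", {
  sp <- ionSpecies(1, 3)
  out <- simulateIsotopeSpectrum(list(sp), weights = 1)
  expect_equal(max(out$profile$intensity), 1)
  sticks <- out$sticks[[1]]@sticks
  gridStep <- diff(out$profile$mz[1:2])
  top <- sticks[sticks$abundance > 0.5, ]
  for (i in seq_len(nrow(top))) {
    near <- out$profile[abs(out$profile$mz - top$mz[i]) < 3 * gridStep, ]
    expect_lt(abs(near$mz[which.max(near$intensity)] - top$mz[i]), gridStep)
  }
  # same formula at different charge: identical stick abundances,
  # m/z spacing (and hence profile width) scaled by 1/z
  p3 <- isotopePattern(insulinFormula(), 3)
  p6 <- isotopePattern(insulinFormula(), 6)
  expect_equal(p3@sticks$abundance, p6@sticks$abundance, tolerance = 1e-9)
  expect_equal(sum(p3@sticks$abundance), sum(p6@sticks$abundance),
               tolerance = 1e-9)
  expect_equal(p6@spacing, p3@spacing / 2, tolerance = 1e-12)
})

test_that("monomer/dimer mixtures interleave sticks at half spacing", {
  mono <- ionSpecies(1, 3); dimr <- ionSpecies(2, 6)
  out <- simulateIsotopeSpectrum(list(mono, dimr), weights = c(0.5, 0.5))
  sp <- vapply(out$sticks, function(p) p@spacing, numeric(1))
  expect_equal(sp[2], sp[1] / 2, tolerance = 1e-12)
  # the dimer contributes sticks between adjacent monomer sticks
  mzM <- out$sticks[[1]]@sticks$mz
  mzD <- out$sticks[[2]]@sticks$mz
  between <- any(mzD > mzM[1] & mzD < mzM[2] &
                   pmin(abs(mzD - mzM[1]), abs(mzD - mzM[2])) > sp[2] / 4)
  expect_true(between)
})

test_that("mixture profiles round-trip through the decomposition", {
  mono <- ionSpecies(1, 3); dimr <- ionSpecies(2, 6)
  out <- simulateIsotopeSpectrum(list(mono, dimr), weights = c(0.7, 0.3),
                                 resolvingPower = 5e4)
  dec <- decomposePattern(out$profile, list(mono, dimr),
                          resolvingPower = 5e4)
  expect_equal(unname(dec$weights), c(0.7, 0.3), tolerance = 0.02)
})

test_that("CID spectra place sticks at fragment m/z and flag coincidences", {
  parent <- ionSpecies(2, 7)
  spec <- simulateCIDSpectrum(parent,
                              setNames(1, "(1,3)+(1,4)"))
  expect_equal(nrow(spec), 2)
  expect_equal(sort(spec$mz),
               sort(c(ionSpecies(1, 3)@mzAvg, ionSpecies(1, 4)@mzAvg)),
               tolerance = 1e-9)
  expect_false(any(spec$indistinguishable))
  # monomer parent: no fission channels
  expect_equal(nrow(simulateCIDSpectrum(ionSpecies(1, 5))), 0)
  # symmetric split of [2M+6H]6+ lands exactly on the parent m/z
  sym <- simulateCIDSpectrum(ionSpecies(2, 6), setNames(1, "(1,3)+(1,3)"))
  expect_true(all(sym$indistinguishable))
  expect_equal(unique(sym$mz), ionSpecies(2, 6)@mzAvg, tolerance = 1e-9)
  expect_error(simulateCIDSpectrum(parent, setNames(1, "(9,9)+(9,9)")),
               "unknown channel")
})
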