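# Species assignment: elemental formulas, isotope fine structure, aggromer
# candidates, NNLS mixture decomposition, CID channels and the verdict rule.

test_that("insulin elemental formula and masses are reproduced", {
  f <- insulinFormula()
  expect_equal(f, c(C = 254, H = 377, N = 65, O = 75, S = 6))
  expect_equal(formulaMass(f, "average"), 5733.6, tolerance = 1e-4)
  expect_equal(formulaMass(f, "monoisotopic"), 5729.6, tolerance = 1e-4)
  # oligomer linearity
  expect_equal(elementalFormula(insulinChains(), 3, n = 2), 2 * f)
  # breaking the disulfides restores exactly six hydrogens
  red <- elementalFormula(insulinChains(), 0)
  expect_equal(red["H"] - f["H"], c(H = 6))
  expect_error(elementalFormula("GIVEB"), "unknown residue")
  expect_error(elementalFormula("GCGC", disulfides = 2), "cysteine")
})

test_that("isotope patterns match a full enumeration on a small formula", {
  # independent oracle: enumerate heavy-isotope counts with binomial weights
  pat <- isotopePattern(c(C = 5, H = 5), z = 1, abundanceFloor = 1e-9)
  pC <- 0.0107; pH <- 0.000115
  expected <- numeric(11)
  for (nC in 0:5) for (nH in 0:5) {
    k <- nC + nH
    expected[k + 1] <- expected[k + 1] +
      dbinom(nC, 5, pC) * dbinom(nH, 5, pH)
  }
  expected <- expected / max(expected)
  got <- pat@sticks$abundance
  expect_equal(got, expected[seq_along(got)], tolerance = 1e-9)
})

test_that("protein-scale patterns shift the most abundant stick off the monoisotopic", {
  pat <- isotopePattern(insulinFormula(), z = 3)
  expect_gt(which.max(pat@sticks$abundance), 1)
  # stick spacing halves when the charge doubles
  p2 <- isotopePattern(insulinFormula(), z = 6)
  expect_equal(p2@spacing, pat@spacing / 2, tolerance = 1e-12)
  expect_equal(diff(pat@sticks$mz),
               rep(pat@spacing, nrow(pat@sticks) - 1), tolerance = 1e-9)
})

test_that("pruning never removes the most abundant stick", {
  set.seed(5)
  for (i in 1:20) {
    f <- c(C = sample(1:300, 1), H = sample(1:400, 1), N = sample(0:60, 1),
           O = sample(0:80, 1), S = sample(0:8, 1))
    f <- f[f > 0]
    pat <- isotopePattern(f, z = sample(1:10, 1), abundanceFloor = 0.5)
    expect_equal(max(pat@sticks$abundance), 1)
  }
})

test_that("aggromer candidates enumerate the m/z-coincident ladder", {
  cand <- coincidentCandidates(1912.2, insulinFormula(), tol = 0.5,
                               nMax = 4, zMax = 12)
  nz <- t(vapply(cand, function(s) c(s@n, s@z), integer(2)))
  expect_equal(nz, rbind(c(1L, 3L), c(2L, 6L), c(3L, 9L), c(4L, 12L)))
  # far from any species: empty
  expect_length(coincidentCandidates(123.4, insulinFormula(), tol = 0.5), 0)
  # average m/z identity mz(kn, kz) = mz(n, z), the degeneracy to break
  s11 <- ionSpecies(1, 3)
  for (k in 2:5)
    expect_equal(ionSpecies(k, 3 * k)@mzAvg, s11@mzAvg, tolerance = 1e-12)
})

test_that("NNLS decomposition recovers pure and mixed inputs", {
  mono <- ionSpecies(1, 3); dimr <- ionSpecies(2, 6)
  pure <- simulateIsotopeSpectrum(list(mono, dimr), weights = c(1, 0))
  dec <- decomposePattern(pure$profile, list(mono, dimr))
  expect_equal(unname(dec$weights), c(1, 0), tolerance = 0.01)
  mixed <- simulateIsotopeSpectrum(list(mono, dimr), weights = c(0.7, 0.3))
  dec2 <- decomposePattern(mixed$profile, list(mono, dimr))
  expect_equal(unname(dec2$weights), c(0.7, 0.3), tolerance = 0.02)
  expect_lt(dec2$residual, 1e-8)
  # identical templates are rejected
  expect_error(decomposePattern(pure$profile, list(mono, mono)),
               "rank-deficient")
})

test_that("CID channels conserve mass and charge and match enumeration", {
  ch27 <- cidChannels(ionSpecies(2, 7))
  expect_true("(1,3)+(1,4)" %in% ch27$label)
  expect_equal(nrow(cidChannels(ionSpecies(1, 5))), 0)
  # [3M+8H]8+: n-split {1,2} x z1 in 1..7 -> 7 channels
  ch38 <- cidChannels(ionSpecies(3, 8))
  expect_equal(nrow(ch38), 7)
  expect_true(all(ch38$n1 + ch38$n2 == 3L & ch38$z1 + ch38$z2 == 8L))
})

test_that("verdict rule separates conformers, aggromers and undetermined", {
  mono3 <- ionSpecies(1, 3); dim6 <- ionSpecies(2, 6); dim7 <- ionSpecies(2, 7)
  # dimer contamination in the pattern + monomer CID fragments from a
  # dimer parent -> aggromer mixture; early peak gets the higher charge
  fams <- simRecover(groundTruth(
    mono3, data.frame(ccs = c(850, 950), abundance = c(0.5, 0.5))),
    kMax = 2)
  v1 <- classifyPeak(
    atdFamilies = fams,
    patternWeights = c("[M+3H]3+" = 0.7, "[2M+6H]6+" = 0.3),
    cidFragmentsObserved = data.frame(n = c(1, 1), z = c(3, 3)),
    nominal = mono3, candidates = list(mono3, dim6))
  expect_equal(v1$verdict, "aggromer_mixture")
  expect_equal(v1$evidence$atd_assignment$species[1], "[2M+6H]6+")
  # pure pattern + monomer-only CID consistent with the dimer parent
  v2 <- classifyPeak(
    patternWeights = c("[2M+7H]7+" = 1.0),
    cidFragmentsObserved = data.frame(n = c(1, 1), z = c(3, 4)),
    nominal = dim7, candidates = list(dim7))
  expect_equal(v2$verdict, "conformers")
  # no evidence at all
  expect_equal(classifyPeak(nominal = dim7)$verdict, "undetermined")
  # contradictory: pattern says pure monomer, CID fragments impossible
  v3 <- classifyPeak(
    patternWeights = c("[M+3H]3+" = 1.0),
    cidFragmentsObserved = data.frame(n = 1, z = 2),
    nominal = mono3, candidates = list(mono3, dim6))
  expect_equal(v3$verdict, "undetermined")
})
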