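---
title: "Characterising protein oligomer conformers by drift-tube ion mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising protein oligomer conformers by drift-tube ion mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtims)
```

## The problem

During the lag phase that precedes amyloid fibril growth, an aggregating
protein such as insulin populates a zoo of transient oligomers
[nM + zH]^z+^. Native ion mobility mass spectrometry separates these by
mass-to-charge *and* by shape, but two species with composition
[knM + kzH]^kz+^ share the *same* average m/z for every k — a dimer with
twice the mass and twice the charge of a monomer is invisible to a
low-resolution mass analyser. A multimodal arrival time distribution (ATD)
at one m/z can therefore mean either several conformations of one species
or a mixture of m/z-coincident oligomers ("aggromers"). `dtims` implements
the full inference chain that resolves this ambiguity and turns arrival
times into collision cross sections (CCS), together with a synthetic
drift-tube instrument so that every stage can be validated against known
ground truth.

## The physics

An ion pulsed into a drift cell of length $L$ filled with helium at
pressure $P$ and temperature $T$ traverses it in

$$t_\mathrm{drift} = \frac{L^2}{K\,V}, \qquad
  K = K_0\,\frac{760}{P}\,\frac{T}{273.15},$$

under drift voltage $V$; the measured arrival time adds an m/z-dependent,
voltage-invariant dead time spent outside the cell. Regressing arrival
time on $P/V$ therefore yields the dead time as the intercept and the
mobility through the slope; with the geometry folded in, the slope is
$1000\,L^2\,273.15/(760\,T\,K_0)$ ms per Torr/V, so $K_0$ comes straight
out of the fit. This folding is deliberate: regressing on $P/V$ (rather
than $1/V$) absorbs pressure drift between runs, and is the only reading
consistent with normalising $K$ by both pressure and temperature.

The Mason–Schamp relation converts reduced mobility into the
momentum-transfer collision integral:

$$\Omega = \frac{3ze}{16N_0}\sqrt{\frac{2\pi}{\mu k_b T}}\,\frac{1}{K_0},$$

with $z$ the charge, $e$ the elementary charge, $N_0$ the buffer-gas
number density at standard conditions, $\mu$ the reduced ion/He mass and
$k_b$ Boltzmann's constant. CODATA values are compiled in
`physicalConstants()`; no constants are fitted. For orientation: $K_0 = 1$
cm^2^V^-1^s^-1^ at $z=1$, $T=300$ K, $\mu=4$ u gives $\Omega = 534.3$ Å^2^.

```{r}
ccsFromReducedMobility(1.0, z = 1, temperature = 300, mu = 4.0)
```

## The synthetic instrument

`simulateATDSet()` emulates a 5.1 cm copper drift cell holding helium at
3.5 Torr — the geometry under which the insulin oligomer measurements were
made — stepped through six drift voltages (25–60 V by default, a factor
2.4 that conditions the $P/V$ regression well). Each conformer family of
each species contributes a Gaussian centred at dead time + drift time
whose area is its ground-truth abundance. Peak widths follow the
diffusion-limited single-peak resolving power
$t/\Delta t = \sqrt{zeV/(16\ln 2\,k_bT)}$, which puts FWHM values in the
tens of microseconds on millisecond drift times — realistic for a
low-field cell. A `widthInflation` factor (default 1, i.e. the diffusion
limit) lets users emulate additional instrumental broadening.

Choices a user should know about:

* **Cell temperature** defaults to 300 K. The instrument is
  temperature-capable but the oligomer data come from ambient runs with no
  stated cell temperature, so room temperature is the natural choice; it
  is exposed in `instrumentConfig()`.
* **Dead time** is modelled as $2.0\sqrt{m/z}$ µs — of the order of 100 µs
  for these ions, m/z-dependent but voltage-invariant, matching how dead
  time behaves in the transfer optics.
* **Time binning** defaults to 2 µs. The simulator refuses to generate
  traces whose bins are wider than half the narrowest peak sigma, since
  such histograms cannot support centroiding; at the study conditions the
  z = 7 dimer peaks have $\sigma_t \approx 7$–30 µs, which fixes the
  usable bin scale. (A coarser bin is accepted whenever the peaks are wide
  enough.)
* **Counting noise** is Poisson per bin, scaled so the tallest bin has a
  chosen expected count; `peakCounts = 0` returns the exact profile. All
  randomness flows from one integer seed recorded in the bundle manifest.

What the generator deliberately does *not* emulate: ion-optics
transmission efficiency, collision-energy-dependent fragmentation, peak
tailing, chloride adduction, or conformer interconversion during drift.
Passing round-trip tests therefore demonstrates that the *inference chain*
is correct, not that real insulin spectra are this clean; on real data the
deconvolution confronts asymmetric peaks and interconverting families that
this model excludes by construction.

## Deconvolution and family tracking

`deconvolveATD()` fits sums of 1–4 Gaussians by Levenberg–Marquardt least
squares. Seeds come from local maxima of a lightly smoothed trace above
`minSnr` × the baseline MAD (default 3×), with ties broken toward earlier
time and a minimum seed separation so counting noise on a peak top cannot
spawn duplicate components. The component count is chosen by an elbow
rule: the smallest k whose residual sum of squares improves by less than
5% when k+1 is tried. Experimentally one usually resolves three families
and occasionally a weakly populated fourth; k is capped at 4 accordingly.

`trackFamilies()` joins components across voltages by arrival-time rank,
not by nearest centroid: at fixed voltage $t \propto 1/K$, so on clean
data the rank order is voltage-invariant by physics. One refinement
matters in practice: a voltage at which the deconvolution found *fewer*
(a merge of the two widest peaks, typically at the lowest voltage) or
*more* (a spurious split) components than the modal count across voltages
cannot be rank-labelled unambiguously, so that voltage contributes no
points rather than rank-shifting every family. Families keep their
remaining points when at least two voltages survive, else they are
dropped with a warning.

`familyCCS()` then runs the per-family $P/V$ regression (unweighted OLS by
default — no error model is assumed for the centroids; a weighted variant
is available through the `weights` argument of `mobilityRegression()`),
converts $K_0$ to CCS, and propagates the slope standard error into the
CCS uncertainty. The reported uncertainty is thus a *fit-propagated*
error; replicate scatter across repeated bundles would be larger and is
the user's to assess.

```{r}
truth <- groundTruth(
  ionSpecies(2, 7),
  data.frame(ccs = c(1217, 1324, 1563, 1701),
             abundance = c(0.50, 0.25, 0.15, 0.10)))
atd <- simulateATDSet(truth, instrumentConfig())
fams <- atdFamilies(atd, z = 7,
                    ionMass = 2 * 5733.55 + 7 * 1.007276466)
vapply(fams, ccs, numeric(1))
```

`compositeDistribution()` pools the families of all charge states of an
oligomer order into one weighted-Gaussian CCS distribution, using
sd = max(fit error, 1% of CCS) — the merge is a visual summary and no
width information survives the pooling, so a nominal width is applied.

## Breaking the aggromer degeneracy

`isotopePattern()` computes isotopologue distributions by convolving the
elemental isotope vectors (IUPAC 2021 abundances) over neutron-count
shifts, placing sticks on the lattice mono-m/z $+ k \cdot 1.00335/z$. The
spacing is the assignment lever: a dimer at twice the mass and charge
shows sticks at exactly *half* the monomer spacing, interleaving with
them. `decomposePattern()` fits an observed high-resolution profile as a
non-negative combination of candidate templates (NNLS), and
`classifyPeak()` combines three evidence streams:

* pattern decomposition — a secondary species above a 5% weight threshold
  (configurable; the experimental reports are qualitative, so the
  threshold is a package choice) indicates an aggromer;
* CID channel logic — `cidChannels()` enumerates all binary fissions
  conserving monomer count and charge; observed fragments impossible for
  the nominal species force a higher-order parent. Only binary fissions
  are enumerated — all observed dissociation of these oligomers is into
  two sub-oligomers — and symmetric channels such as
  [2M+6H]^6+^ → 2 × [M+3H]^3+^ are flagged parent-indistinguishable;
* with neither stream available, or with the two in contradiction, the
  verdict is `undetermined` rather than a guess.

When an aggromer is present, the earlier-arriving ATD component is
assigned to the higher-charge species, since the deeper potential drop
makes the higher charge state faster.

## Charge limits and structure metrics

`rayleighLimit()` implements the empirical maximum native-fold charge
$z_R = 0.0778\sqrt{M}$ (mass in u). Oligomers observed *below* their limit
can be read as solution conformers; those above it (for insulin: the 6+
monomer and the 9+ dimer, and no others) are candidates for coulombically
driven gas-phase unfolding and are excluded from solution inference.
Average masses are used; at several kDa the average/monoisotopic
difference shifts $z_R$ by well under 0.1 charge.

On the structure side, `radiusOfGyration()`, `kabschRMSD()` (SVD
superposition with the proper-rotation determinant correction) and
`paCCS()` connect atomistic models to the mobility axis. `paCCS()` is a
projection approximation: the orientation-averaged area of the projected
union of atom spheres (Bondi radii) inflated by a 1.0 Å helium probe,
computed by strip integration that is exact along one axis and discretised
at 0.1 Å along the other, over uniformly random rotations drawn from unit
quaternions. PA systematically underestimates trajectory-method CCS for
concave surfaces — typically by several percent on protein dimers — and is
reported with its Monte-Carlo standard error so users can trade
orientation count against precision. `rgCcsRegression()` formalises the
linear Rg–CCS calibration observed for conformer ensembles, and
`quartileResponse()` reports a response (e.g. β-strand content) over
compact-to-extended Rg quartiles with bin sizes differing by at most one.
`cuboidRg()` gives the uniform-cuboid $R_g=\sqrt{(a^2+b^2+c^2)/12}$ used
for box models of protofilament cross-sections; note that a 30 × 40 Å
cross-section alone gives 14.4 Å, so any larger literature estimate embeds
an assumption about the third dimension that the user must supply
explicitly.

## Numerical choices and limitations

* Gaussian mixture fits parameterise $\log\sigma$ to keep widths positive;
  non-convergence falls back to the best smaller k, and a trace with
  nothing above threshold returns an empty component list.
* The elbow threshold (5%) and SNR threshold (3× MAD) are deterministic,
  so identical inputs and seeds give byte-identical outputs
  (`runPipeline()` asserts this in its tests).
* Isotope convolution uses binary exponentiation with tail pruning at
  1e-12; pruning to the reporting floor keeps the contiguous block around
  the most abundant stick so stick spacing stays uniform.
* Problem sizes in the test-suite round trips — six voltages, traces of a
  few thousand 2 µs bins, 20–24 Poisson replicates at 2000 peak counts,
  a few hundred PA orientations — were chosen as the smallest ensembles
  at which recovered quantities sit well inside their tolerances.
* Non-Gaussian (tailing) peaks, travelling-wave calibration, high-field
  mobility, and conformer interconversion during drift are out of scope;
  CCS values measured on interconverting families under-represent the
  true conformational spread, and the package does not attempt to model
  that.
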