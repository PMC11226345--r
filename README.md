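# dtims — drift-tube ion mobility analysis of protein oligomer assembly

`dtims` is an R package for scientists who use native drift-tube ion
mobility mass spectrometry (IM-MS) to characterise the transient protein
oligomers that populate the amyloid lag phase. During early aggregation a
protein such as insulin forms oligomers [nM + zH]^z+ whose arrival time
distributions (ATDs) are often multimodal — and a peak at one m/z can hide
either several conformations of one species or an "aggromer": an oligomer
[knM + kzH]^kz+ that shares the same average m/z for every k. The package
implements the complete inference chain that resolves this ambiguity and
assigns collision cross sections (CCS) to every conformer family, plus a
synthetic drift-tube instrument so that each stage is testable against
known ground truth without real spectra.

## What it computes

**Mobility physics.** Arrival time is dead time (m/z-dependent,
voltage-invariant) plus drift time `L²/(K V)`. Regressing arrival time on
P/V gives the dead time (intercept) and the reduced mobility K₀ (slope),
which the Mason–Schamp relation converts to the momentum-transfer
collision integral:

    Ω = (3 z e)/(16 N₀) · √(2π/(μ k_b T)) · 1/K₀

with z the charge, μ the reduced ion/He mass, and N₀ the buffer-gas number
density at standard conditions (CODATA constants throughout).

**The pipeline.** `simulateATDSet()` emulates a 5.1 cm helium drift cell
at 3.5 Torr stepped through six drift voltages, with diffusion-limited
peak widths and Poisson counting noise; `deconvolveATD()` fits Gaussian
mixtures with an elbow rule (up to four conformer families);
`trackFamilies()` joins components across voltages by arrival-time rank;
`familyCCS()` turns each family into a CCS with a fit-propagated error;
`isotopePattern()` / `decomposePattern()` / `cidChannels()` /
`classifyPeak()` decide conformers vs aggromers from isotope fine
structure (stick spacing 1.00335/z) and collision-induced dissociation
channel logic; `rayleighLimit()` screens charge states against the
empirical native-fold maximum z_R = 0.0778·√M; and `radiusOfGyration()`,
`paCCS()`, `kabschRMSD()`, `rgCcsRegression()`, `quartileResponse()` and
`cuboidRg()` connect atomistic structures to the mobility axis. The
bovine insulin chains (A: 21 aa, B: 30 aa, three disulfides;
C254H377N65O75S6, 5733.6 u average) ship as a FASTA fixture.
`runPipeline()` chains everything with one seed and writes
families.tsv, ccs.tsv, verdicts.json, limits.tsv and composite.json.

## Worked example

Simulate the four-family insulin dimer [2M+7H]7+ with Poisson counting
noise (2000 counts at the tallest peak) and recover every family:

```r
library(dtims)

truth <- groundTruth(
  ionSpecies(2, 7),
  data.frame(ccs = c(1217, 1324, 1563, 1701),
             abundance = c(0.50, 0.25, 0.15, 0.10)),
  noise = noiseModel(peakCounts = 2000, seed = 42))
atd <- simulateATDSet(truth, instrumentConfig())
atd
#> ATDSet at m/z 1639.16: 6 traces, V = 25, 32, 39, 46, 53, 60

fams <- atdFamilies(atd, z = 7, ionMass = 2 * 5733.55 + 7 * 1.007276466)
for (f in fams) show(f)
#> ConformerFamily rank 1: CCS 1217.2 +/- 0.12 A2, abundance 0.498
#> ConformerFamily rank 2: CCS 1324.2 +/- 0.21 A2, abundance 0.251
#> ConformerFamily rank 3: CCS 1562.7 +/- 0.31 A2, abundance 0.151
#> ConformerFamily rank 4: CCS 1700.7 +/- 0.31 A2, abundance 0.100

fams[[1]]@fit
#> MobilityFit: K0 = 3.0725 +/- 0.0003146 cm2/V/s, dead time 0.0809 ms, R2 = 1.000000 (n = 6)
```

Each family's CCS comes back within a fraction of a percent of truth even
under counting noise, with the most compact conformer the most abundant —
the signature of lag-phase oligomer ensembles. The Rayleigh screen then
says which charge states can be read as solution conformers:

```r
flagSpecies(list(ionSpecies(1, 6), ionSpecies(2, 7), ionSpecies(2, 9)))
#>       label      M_R z_obs      z_R exceeds
#> 1  [M+6H]6+  5733.55     6 5.891032    TRUE
#> 2 [2M+7H]7+ 11467.10     7 8.331178   FALSE
#> 3 [2M+9H]9+ 11467.10     9 8.331178    TRUE
```

The 6+ monomer and 9+ dimer exceed their limits (candidates for gas-phase
coulombic unfolding); the 7+ dimer does not, so its four families reflect
solution structure.

## Vignette

`vignettes/drift-tube-oligomer-analysis.Rmd` documents the model, the
synthetic-instrument assumptions, every tunable threshold, and the known
limitations (what passing round-trip tests do and do not demonstrate
about real spectra).
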