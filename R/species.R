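## Species assignment: elemental formulas, isotope fine structure, aggromer
## candidates, mixture decomposition, CID channel bookkeeping and the
## conformers-vs-aggromers decision rule.

#' Elemental formula of a disulfide-bonded protein oligomer
#'
#' Sums residue formulas over all chains, adds one water per chain, removes
#' two hydrogens per disulfide bond, and multiplies by the oligomer order.
#'
#' @param chains character vector of one-letter residue strings
#' @param disulfides number of disulfide bonds per monomer
#' @param n oligomer order
#' @return Named numeric vector of element counts (C, H, N, O, S).
#' @examples
#' elementalFormula(insulinChains(), disulfides = 3)
#' @export
elementalFormula <- function(chains, disulfides = 0L, n = 1L) {
  f <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  nCys <- 0L
  for (ch in chains) {
    aa <- strsplit(toupper(ch), "")[[1]]
    bad <- setdiff(aa, names(.RESIDUES))
    if (length(bad))
      stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
    for (a in aa) f <- f + .RESIDUES[[a]]
    nCys <- nCys + sum(aa == "C")
    f <- f + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # terminal H2O
  }
  if (disulfides > nCys %/% 2L)
    stop("more disulfides than available cysteine pairs")
  f["H"] <- f["H"] - 2 * disulfides
  f * n
}

#' Bovine insulin chain sequences
#'
#' Chain A (21 residues) and chain B (30 residues), read from the packaged
#' FASTA fixture.
#'
#' @return Named character vector of the two chains.
#' @export
insulinChains <- function() {
  path <- system.file("extdata", "bovine_insulin.fasta", package = "dtims")
  seqs <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Bovine insulin monomer formula
#'
#' Chains A + B with the three native disulfide bridges intact.
#'
#' @return Named element-count vector (C254 H377 N65 O75 S6).
#' @export
insulinFormula <- function() {
  elementalFormula(insulinChains(), disulfides = 3L, n = 1L)
}

## k-fold self-convolution of an abundance vector by binary exponentiation,
## pruning mass tails below `tol` of the running maximum.
.polyPower <- function(p, k, tol = 1e-12) {
  out <- 1
  base <- p
  while (k > 0) {
    if (k %% 2 == 1) out <- .polyProd(out, base, tol)
    k <- k %/% 2
    if (k > 0) base <- .polyProd(base, base, tol)
  }
  out
}

.polyProd <- function(a, b, tol) {
  r <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    r[idx] <- r[idx] + a[i] * b
  }
  keep <- which(r > max(r) * tol)
  r[seq_len(max(keep))]
}

#' Isotopologue pattern of a formula at charge z
#'
#' Convolves the elemental isotope-abundance vectors over neutron-count
#' shifts. Sticks sit on the lattice mono m/z + k * 1.0033548378/z, so
#' adjacent sticks are spaced by exactly the 13C spacing over the charge —
#' the property that distinguishes an [nM+zH]z+ ion from its m/z-coincident
#' [2nM+2zH]2z+ aggromer.
#'
#' @param formula named element-count vector
#' @param z charge
#' @param abundanceFloor sticks below this fraction of the maximum are
#'   pruned (the most abundant stick is always kept)
#' @return An \linkS4class{IsotopePattern}.
#' @examples
#' isotopePattern(insulinFormula(), z = 3)
#' @export
isotopePattern <- function(formula, z, abundanceFloor = 1e-3) {
  z <- as.integer(z)
  if (z < 1L) stop("z must be >= 1")
  formula <- formula[formula > 0]
  if (!length(formula)) stop("empty formula")
  bad <- setdiff(names(formula), names(.ELEMENTS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  dist <- 1
  for (el in names(formula))
    dist <- .polyProd(dist, .polyPower(.ELEMENTS[[el]]$ab, formula[[el]]),
                      1e-12)
  dist <- dist / max(dist)
  pm <- physicalConstants()$proton_mass
  monoMz <- (formulaMass(formula, "monoisotopic") + z * pm) / z
  spacing <- .NEUTRON_SPACING / z
  mz <- monoMz + (seq_along(dist) - 1L) * spacing
  keep <- dist >= abundanceFloor
  keep[which.max(dist)] <- TRUE
  ## keep the contiguous block around the maximum so spacing stays uniform
  idx <- which(keep)
  idx <- seq(min(idx), max(idx))
  new("IsotopePattern",
      sticks = data.frame(mz = mz[idx], abundance = dist[idx]),
      charge = z, spacing = spacing)
}

#' Enumerate m/z-coincident oligomer candidates
#'
#' All [nM+zH]z+ whose average m/z lies within \code{tol} of an observed
#' peak. Any species and its "aggromers" [knM+kzH]kz+ share the same average
#' m/z exactly, so a nominal monomer peak always admits the whole ladder.
#'
#' @param mzObs observed average m/z
#' @param monomerFormula monomer element counts
#' @param tol m/z tolerance
#' @param nMax maximum oligomer order scanned
#' @param zMax maximum charge scanned
#' @return List of \linkS4class{IonSpecies}, sorted by n (possibly empty).
#' @examples
#' coincidentCandidates(1912.2, insulinFormula(), tol = 0.5, nMax = 4)
#' @export
coincidentCandidates <- function(mzObs, monomerFormula, tol = 0.5,
                                 nMax = 12L, zMax = 24L) {
  if (tol <= 0) stop("tol must be > 0")
  pm <- physicalConstants()$proton_mass
  M <- formulaMass(monomerFormula, "average")
  out <- list()
  for (n in seq_len(nMax)) for (z in seq_len(zMax)) {
    mz <- (n * M + z * pm) / z
    if (abs(mz - mzObs) <= tol)
      out[[length(out) + 1L]] <- ionSpecies(n, z, monomerFormula)
  }
  out[order(vapply(out, function(s) s@n, integer(1)))]
}

## Gaussian-broadened template of an isotope pattern on an m/z grid.
.patternProfile <- function(pattern, grid, resolvingPower) {
  st <- pattern@sticks
  y <- numeric(length(grid))
  for (i in seq_len(nrow(st))) {
    sigma <- st$mz[i] / resolvingPower / 2.3548200450309493
    y <- y + st$abundance[i] * stats::dnorm(grid, st$mz[i], sigma)
  }
  y
}

#' Decompose an observed isotope profile into candidate species weights
#'
#' Non-negative least squares of the observed profile on Gaussian-broadened
#' template profiles of each candidate's isotope pattern (the fine-structure
#' analogue of fitting predicted distributions to a high-resolution
#' spectrum).
#'
#' @param observed data.frame with columns \code{mz}, \code{intensity}
#' @param candidates list of \linkS4class{IonSpecies}
#' @param resolvingPower instrument resolving power (FWHM definition)
#' @param abundanceFloor floor passed to \code{\link{isotopePattern}}
#' @return List with \code{weights} (normalised, named by candidate label),
#'   \code{raw} coefficients and \code{residual} (relative L2 residual).
#' @export
decomposePattern <- function(observed, candidates, resolvingPower = 5e4,
                             abundanceFloor = 1e-3) {
  if (!length(candidates)) stop("need >= 1 candidate")
  if (!nrow(observed)) stop("observed profile is empty")
  grid <- observed$mz
  A <- vapply(candidates, function(sp) {
    pat <- isotopePattern(sp@formula * sp@n, sp@z, abundanceFloor)
    prof <- .patternProfile(pat, grid, resolvingPower)
    if (max(prof) > 0) prof / max(prof) else prof
  }, numeric(length(grid)))
  A <- as.matrix(A)
  if (qr(A)$rank < ncol(A))
    stop("rank-deficient template set: candidate patterns are not distinct")
  b <- observed$intensity
  sol <- pracma::lsqnonneg(A, b)
  w <- sol$x
  res <- sqrt(sum((b - A %*% w)^2)) / sqrt(sum(b^2))
  wn <- if (sum(w) > 0) w / sum(w) else w
  names(wn) <- vapply(candidates, function(s) s@label, character(1))
  list(weights = wn, raw = w, residual = res)
}

#' Enumerate binary CID fission channels of a multimer
#'
#' All unordered splits of [nM+zH]z+ into two sub-oligomers conserving both
#' monomer count and charge: n1+n2 = n, z1+z2 = z, all >= 1. Channels with a
#' fragment whose m/z equals the parent's (within 0.01) are flagged
#' parent-indistinguishable — e.g. [2M+6H]6+ -> 2 x [M+3H]3+ lands exactly
#' on the parent m/z.
#'
#' @param parent an \linkS4class{IonSpecies}
#' @return data.frame with columns n1, z1, n2, z2, mz1, mz2, label,
#'   indistinguishable. Empty for a monomer.
#' @examples
#' cidChannels(ionSpecies(2, 7))
#' @export
cidChannels <- function(parent) {
  n <- parent@n; z <- parent@z
  pm <- physicalConstants()$proton_mass
  M <- parent@monomerMassAvg
  rows <- list()
  if (n >= 2L) {
    for (n1 in 1:(n %/% 2)) {
      n2 <- n - n1
      for (z1 in 1:(z - 1L)) {
        z2 <- z - z1
        if (n1 == n2 && z1 > z2) next  # unordered
        rows[[length(rows) + 1L]] <- data.frame(n1 = n1, z1 = z1,
                                                n2 = n2, z2 = z2)
      }
    }
  }
  if (!length(rows))
    return(data.frame(n1 = integer(0), z1 = integer(0), n2 = integer(0),
                      z2 = integer(0), mz1 = numeric(0), mz2 = numeric(0),
                      label = character(0), indistinguishable = logical(0)))
  ch <- do.call(rbind, rows)
  ch$mz1 <- (ch$n1 * M + ch$z1 * pm) / ch$z1
  ch$mz2 <- (ch$n2 * M + ch$z2 * pm) / ch$z2
  ch$label <- sprintf("(%d,%d)+(%d,%d)", ch$n1, ch$z1, ch$n2, ch$z2)
  ch$indistinguishable <- abs(ch$mz1 - parent@mzAvg) <= 0.01 |
    abs(ch$mz2 - parent@mzAvg) <= 0.01
  ch
}

## Can (nf, zf) be a fragment of `species` under binary fission?
.isPossibleFragment <- function(species, nf, zf) {
  ch <- cidChannels(species)
  if (!nrow(ch)) return(FALSE)
  any((ch$n1 == nf & ch$z1 == zf) | (ch$n2 == nf & ch$z2 == zf))
}

#' Classify a multimodal ATD peak as conformers or an aggromer mixture
#'
#' Applies the two-evidence decision rule: an m/z peak with multiple ATD
#' components is an aggromer mixture if the isotope-pattern decomposition
#' gives a secondary species at least \code{threshold} weight, or if observed
#' CID fragments are impossible for the nominal species (and hence require a
#' higher-order parent). Otherwise the components are conformer families of
#' one species. With no usable evidence — or contradictory evidence — the
#' verdict is undetermined. When an aggromer is present, the
#' earlier-arriving ATD component is assigned to the higher-charge species
#' (higher charge means higher mobility and hence earlier arrival).
#'
#' @param atdFamilies list of \linkS4class{ConformerFamily} (or NULL)
#' @param patternWeights named weight vector from
#'   \code{\link{decomposePattern}} (or NULL if no high-resolution spectrum)
#' @param cidFragmentsObserved data.frame with columns n, z of observed
#'   fragment ions (or NULL if no CID data)
#' @param nominal the nominal \linkS4class{IonSpecies} of the peak
#' @param candidates list of candidate species matching
#'   \code{patternWeights} (first is taken as the nominal assignment)
#' @param threshold secondary-species weight needed to call an aggromer
#' @return List (verdict record) with fields \code{verdict} ("conformers",
#'   "aggromer_mixture" or "undetermined"), \code{weights}, and an
#'   \code{evidence} list carrying the pattern residual and CID consistency.
#' @export
classifyPeak <- function(atdFamilies = NULL, patternWeights = NULL,
                         cidFragmentsObserved = NULL, nominal,
                         candidates = NULL, threshold = 0.05) {
  hasPattern <- !is.null(patternWeights) && length(patternWeights) > 0
  hasCid <- !is.null(cidFragmentsObserved)
  if (!hasPattern && !hasCid)
    return(list(verdict = "undetermined", weights = NULL,
                evidence = list(reason = "no evidence streams")))

  secondary <- 0
  if (hasPattern) {
    nomLabel <- nominal@label
    others <- patternWeights[setdiff(names(patternWeights), nomLabel)]
    secondary <- if (length(others)) max(others) else 0
  }
  patternSaysMixture <- hasPattern && secondary >= threshold

  cidRequiresHigher <- FALSE
  if (hasCid && nrow(cidFragmentsObserved)) {
    possible <- vapply(seq_len(nrow(cidFragmentsObserved)), function(i)
      .isPossibleFragment(nominal, cidFragmentsObserved$n[i],
                          cidFragmentsObserved$z[i]), logical(1))
    cidRequiresHigher <- any(!possible)
  }

  evidence <- list(secondary_weight = secondary,
                   cid_requires_higher_order = cidRequiresHigher)

  if (hasPattern && hasCid && !patternSaysMixture && cidRequiresHigher &&
      secondary < threshold / 5)
    return(list(verdict = "undetermined", weights = patternWeights,
                evidence = c(evidence, list(
                  reason = "pattern pure but CID fragments impossible for nominal species"))))

  if (patternSaysMixture || cidRequiresHigher) {
    w <- patternWeights
    if (is.null(w) && !is.null(candidates)) {
      w <- stats::setNames(rep(1 / length(candidates), length(candidates)),
                           vapply(candidates, function(s) s@label,
                                  character(1)))
    }
    ## earlier-arriving ATD component <- higher-charge species
    assignment <- NULL
    if (!is.null(atdFamilies) && length(atdFamilies) >= 2 &&
        !is.null(candidates) && length(candidates) >= 2) {
      zs <- vapply(candidates, function(s) s@z, integer(1))
      ord <- order(zs, decreasing = TRUE)  # high charge arrives first
      k <- min(length(atdFamilies), length(candidates))
      assignment <- data.frame(
        rank = vapply(atdFamilies[seq_len(k)], function(f) f@rank,
                      integer(1)),
        species = vapply(candidates[ord][seq_len(k)],
                         function(s) s@label, character(1)))
    }
    return(list(verdict = "aggromer_mixture", weights = w,
                evidence = c(evidence, list(atd_assignment = assignment))))
  }

  list(verdict = "conformers",
       weights = stats::setNames(1, nominal@label), evidence = evidence)
}
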