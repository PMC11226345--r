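## Structure-side metrics: radius of gyration, projection-approximation
## CCS, Kabsch RMSD, the Rg-CCS calibration, the Rg-quartile response
## statistic and the uniform-cuboid Rg estimate.

#' Read a PDB file into a StructureModel
#'
#' First model only; alternate locations resolved to 'A'; hydrogens kept if
#' present. Masses and Bondi radii are assigned from element symbols.
#'
#' @param file path to a PDB file
#' @param label text label (default the file name)
#' @return A \linkS4class{StructureModel}.
#' @export
readPDBModel <- function(file, label = basename(file)) {
  pdb <- bio3d::read.pdb(file, multi = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(gsub("[0-9 ]", "", at$elety), 1, 1)
  el <- trimws(el)
  el[el == ""] <- "C"
  structureModel(cbind(at$x, at$y, at$z), element = el, label = label)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from the centre of
#' mass.
#'
#' @param model a \linkS4class{StructureModel}
#' @return Rg in Angstrom.
#' @examples
#' radiusOfGyration(structureModel(rbind(c(-1, 0, 0), c(1, 0, 0))))
#' @export
radiusOfGyration <- function(model) {
  m <- model@mass
  if (sum(m) <= 0) stop("zero total mass")
  com <- colSums(model@xyz * m) / sum(m)
  d2 <- rowSums(sweep(model@xyz, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

## Uniform random rotation matrices from unit quaternions.
.randomRotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

## Area of the union of disks (cx, cy, r) by strip integration: for each
## x-strip the union of y-intervals is merged exactly; only the x axis is
## discretised.
.diskUnionArea <- function(cx, cy, r, step) {
  x0 <- min(cx - r); x1 <- max(cx + r)
  xs <- seq(x0 + step / 2, x1, by = step)
  area <- 0
  for (x in xs) {
    dx2 <- (x - cx)^2
    hit <- which(dx2 < r^2)
    if (!length(hit)) next
    w <- sqrt(r[hit]^2 - dx2[hit])
    lo <- cy[hit] - w; hi <- cy[hit] + w
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    tot <- 0; curLo <- lo[1]; curHi <- hi[1]
    if (length(lo) > 1) {
      for (i in 2:length(lo)) {
        if (lo[i] <= curHi) curHi <- max(curHi, hi[i])
        else { tot <- tot + curHi - curLo; curLo <- lo[i]; curHi <- hi[i] }
      }
    }
    tot <- tot + curHi - curLo
    area <- area + tot * step
  }
  area
}

#' Projection-approximation collision cross section
#'
#' Orientation-averaged projected area of the union of atom spheres
#' inflated by the probe radius: the projected union area is computed for
#' uniformly random rotations (strip integration, exact in one axis) and
#' averaged. The Monte-Carlo standard error of the mean is reported. The
#' projection approximation systematically underestimates trajectory-method
#' CCS for concave surfaces; it is the standard desk-scale estimate.
#'
#' @param model a \linkS4class{StructureModel}
#' @param probeRadius buffer-gas probe radius in Angstrom (He ~ 1.0)
#' @param nOrientations number of random orientations (>= 100)
#' @param seed integer seed for the orientation sample
#' @param gridStep strip width in Angstrom
#' @return List with \code{ccs} (Angstrom^2), \code{stderr}, \code{n}.
#' @examples
#' paCCS(structureModel(matrix(0, 1, 3), radius = 1), probeRadius = 1)
#' @export
paCCS <- function(model, probeRadius = 1.0, nOrientations = 300L,
                  seed = 1L, gridStep = 0.1) {
  if (nOrientations < 100L) stop("nOrientations must be >= 100")
  r <- model@radius + probeRadius
  xyz <- model@xyz
  set.seed(seed)
  rots <- .randomRotations(nOrientations)
  areas <- vapply(rots, function(R) {
    p <- xyz %*% t(R)
    .diskUnionArea(p[, 1], p[, 2], r, gridStep)
  }, numeric(1))
  list(ccs = mean(areas), stderr = stats::sd(areas) / sqrt(length(areas)),
       n = nOrientations)
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' RMSD between two structures after the optimal rigid superposition
#' (translation plus proper rotation via SVD with determinant correction).
#'
#' @param a,b \linkS4class{StructureModel}s
#' @param subset optional atom index vector applied to both
#' @return RMSD in Angstrom.
#' @export
kabschRMSD <- function(a, b, subset = NULL) {
  P <- a@xyz; Q <- b@xyz
  if (!is.null(subset)) { P <- P[subset, , drop = FALSE]
                          Q <- Q[subset, , drop = FALSE] }
  if (nrow(P) != nrow(Q)) stop("subset sizes differ")
  if (nrow(P) < 3L) stop("need >= 3 atoms")
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Q - P %*% t(R))^2)))
}

#' Linear calibration of CCS against radius of gyration
#'
#' OLS fit of CCS (Angstrom^2) on Rg (Angstrom) with the Pearson
#' correlation, plus a prediction helper, formalising the observed linear
#' relation between the two order parameters for conformer ensembles.
#'
#' @param pairs data.frame with columns \code{rg}, \code{ccs}
#' @return List with slope (Angstrom^2/Angstrom), intercept (Angstrom^2),
#'   pearson_r, n, and \code{predict(rg)}.
#' @export
rgCcsRegression <- function(pairs) {
  stopifnot(all(c("rg", "ccs") %in% names(pairs)))
  if (length(unique(pairs$rg)) < 2L) stop("need >= 2 distinct Rg values")
  fit <- stats::lm(ccs ~ rg, data = pairs)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       pearson_r = stats::cor(pairs$rg, pairs$ccs), n = nrow(pairs),
       predict = function(rg) unname(co[1] + co[2] * rg))
}

#' Quartile means of a response over an Rg-ordered ensemble
#'
#' Sorts the ensemble by Rg ascending (most compact first), splits it into
#' four bins whose sizes differ by at most one, and returns the mean
#' response per bin — e.g. beta-strand content per compactness quartile.
#'
#' @param rg numeric vector of radii of gyration
#' @param response numeric response (same length)
#' @return List with \code{means} (length 4, compact to extended),
#'   \code{edges} (Rg range per bin) and \code{sizes}.
#' @examples
#' quartileResponse(10:17, c(8, 8, 6, 6, 4, 4, 2, 2))$means
#' @export
quartileResponse <- function(rg, response) {
  if (length(rg) != length(response)) stop("length mismatch")
  n <- length(rg)
  if (n < 4L) stop("need >= 4 samples")
  o <- order(rg)
  rg <- rg[o]; response <- response[o]
  base <- n %/% 4L; extra <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= extra)
  idx <- split(seq_len(n), rep(1:4, times = sizes))
  list(means = vapply(idx, function(i) mean(response[i]), numeric(1)),
       edges = t(vapply(idx, function(i) range(rg[i]), numeric(2))),
       sizes = sizes)
}

#' Radius of gyration of a uniform rectangular cuboid
#'
#' Rg = sqrt((a^2 + b^2 + c^2) / 12). Degenerate edges (zero) give the
#' lamina and rod limits; useful for box-model estimates of protofilament
#' building blocks from electron-density dimensions.
#'
#' @param a,b,c edge lengths in Angstrom (>= 0, not all zero)
#' @return Rg in Angstrom.
#' @examples
#' cuboidRg(30, 40, 0)  # ~14.43
#' @export
cuboidRg <- function(a, b, c = 0) {
  if (any(c(a, b, c) < 0) || all(c(a, b, c) == 0))
    stop("edges must be >= 0 with at least one > 0")
  sqrt((a^2 + b^2 + c^2) / 12)
}
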