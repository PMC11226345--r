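## ATD deconvolution: Gaussian-mixture fitting of arrival-time traces,
## cross-voltage family tracking, per-family CCS assignment and the
## composite per-oligomer CCS distribution.

## Local maxima of a trace above a threshold, ties broken toward earlier
## time; returns indices sorted by decreasing height. Seeds closer than
## minSep bins to an already accepted (higher) maximum are discarded so
## counting noise on a peak top does not spawn duplicate components.
.localMaxima <- function(y, threshold, minSep = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  idx <- idx[y[idx] > threshold]
  idx <- idx[order(-y[idx], idx)]
  keep <- integer(0)
  for (i in idx)
    if (!length(keep) || all(abs(keep - i) >= minSep))
      keep <- c(keep, i)
  keep
}

## Light running-mean smoothing for seed detection only (fits use raw data).
.smoothTrace <- function(y, w = 5L) {
  if (length(y) < w) return(y)
  as.numeric(stats::filter(y, rep(1 / w, w), sides = 2)) |>
    (\(s) { s[is.na(s)] <- y[is.na(s)]; s })()
}

## Sum-of-Gaussians model matrix-free residual fit via nlsLM for fixed k.
.fitMixture <- function(t, y, centers, sigmas, amps) {
  k <- length(centers)
  par <- c(amps, centers, log(sigmas))
  names(par) <- c(paste0("a", 1:k), paste0("c", 1:k), paste0("ls", 1:k))
  form <- paste0(
    vapply(1:k, function(i)
      sprintf("a%d * exp(-(t - c%d)^2 / (2 * exp(ls%d)^2))", i, i, i),
      character(1)),
    collapse = " + ")
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(paste("y ~", form)),
                      data = data.frame(t = t, y = y), start = as.list(par),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  comp <- data.frame(centroid = co[paste0("c", 1:k)],
                     sigma = exp(co[paste0("ls", 1:k)]),
                     amp = co[paste0("a", 1:k)])
  comp$area <- comp$amp * comp$sigma * sqrt(2 * pi)
  list(components = comp, rss = sum(stats::resid(fit)^2))
}

#' Deconvolve one arrival-time trace into Gaussian components
#'
#' Fits sums of 1..\code{kMax} Gaussians by Levenberg-Marquardt least
#' squares, seeding centroids at local maxima above the signal-to-noise
#' threshold (3 x baseline MAD by default), and selects the smallest
#' component count whose residual sum of squares improves by less than 5
#' percent on increment (elbow rule). Components are returned sorted by
#' centroid with non-negative areas.
#'
#' @param trace list with fields \code{time_ms}, \code{intensity}
#' @param kMax maximum number of components (1-4)
#' @param minSnr detection threshold in units of the baseline MAD
#' @param elbow fractional RSS improvement below which an extra component
#'   is rejected
#' @return data.frame with columns centroid (ms), sigma (ms), area; zero
#'   rows when nothing rises above the threshold.
#' @export
deconvolveATD <- function(trace, kMax = 4L, minSnr = 3, elbow = 0.05) {
  stopifnot(kMax >= 1L, kMax <= 4L)
  t <- trace$time_ms; y <- trace$intensity
  if (!length(t)) stop("empty trace")
  noiseScale <- stats::mad(y, center = stats::median(y))
  threshold <- minSnr * max(noiseScale, max(y) * 1e-9, .Machine$double.eps)
  ys <- .smoothTrace(y)
  binW <- stats::median(diff(t))
  sigma0 <- max(3 * binW, binW)
  maxima <- .localMaxima(ys, threshold, minSep = 6L)
  if (!length(maxima))
    return(data.frame(centroid = numeric(0), sigma = numeric(0),
                      area = numeric(0)))

  best <- NULL; prevRss <- Inf
  for (k in seq_len(kMax)) {
    if (k <= length(maxima)) {
      seeds <- sort(t[maxima[seq_len(k)]])
    } else if (!is.null(best)) {
      ## seed the extra component at the largest remaining residual
      resid <- y
      for (i in seq_len(nrow(best$components)))
        resid <- resid - best$components$amp[i] *
          exp(-(t - best$components$centroid[i])^2 /
                (2 * best$components$sigma[i]^2))
      seeds <- sort(c(best$components$centroid, t[which.max(resid)]))
    } else break
    amps <- stats::approx(t, y, xout = seeds, rule = 2)$y
    amps[amps <= 0] <- max(y) * 0.01
    fit <- .fitMixture(t, y, seeds, rep(sigma0, k), amps)
    if (is.null(fit)) {
      if (is.null(best)) stop("mixture fit failed to converge")
      break
    }
    if (!is.null(best)) {
      improvement <- (prevRss - fit$rss) / prevRss
      if (!is.finite(improvement) || improvement < elbow) break
    }
    best <- fit; prevRss <- fit$rss
    if (fit$rss <= .Machine$double.eps * sum(y^2)) break
  }
  comp <- best$components
  comp <- comp[comp$area > 0, , drop = FALSE]
  comp <- comp[order(comp$centroid), c("centroid", "sigma", "area")]
  rownames(comp) <- NULL
  comp
}

#' Track components across drift voltages into conformer families
#'
#' Components are matched by arrival-time rank: on noise-free data the rank
#' order is voltage-invariant because drift time is proportional to 1/K at
#' every voltage, so the k-th earliest component at each voltage belongs to
#' family k. Families missing a component at some voltage keep their
#' remaining points if at least two survive; otherwise they are dropped
#' with a warning.
#'
#' @param perVoltage named list mapping voltage to a component data.frame
#'   from \code{\link{deconvolveATD}}; names are the voltages
#' @param pressure drift-cell pressure (Torr) attached to every point
#' @return List of family skeletons: each a data.frame with columns V, P,
#'   t, sigma, area, plus a \code{frac} column of the within-voltage area
#'   fraction.
#' @export
trackFamilies <- function(perVoltage, pressure) {
  if (length(perVoltage) < 2L) stop("need components at >= 2 voltages")
  vs <- as.numeric(names(perVoltage))
  counts <- vapply(perVoltage, nrow, integer(1))
  if (any(abs(diff(counts[order(vs)])) > 1L))
    warning("component counts differ by more than 1 between adjacent voltages; rank matching applied")
  ## rank labels are only unambiguous where the full component set resolved:
  ## voltages with fewer (a merge) or more (a split) components than the
  ## modal count contribute no points
  tabC <- table(counts)
  modal <- max(as.integer(names(tabC)[tabC == max(tabC)]))
  if (any(counts != modal)) {
    warning(sum(counts != modal),
            " voltage(s) with non-modal component count skipped")
    perVoltage <- perVoltage[counts == modal]
    vs <- vs[counts == modal]
    counts <- counts[counts == modal]
  }
  if (length(perVoltage) < 2L)
    stop("fewer than 2 voltages with a consistent component count")
  kFam <- max(counts)
  fams <- vector("list", kFam)
  for (k in seq_len(kFam)) {
    rows <- list()
    for (i in seq_along(perVoltage)) {
      comp <- perVoltage[[i]]
      if (nrow(comp) >= k) {
        rows[[length(rows) + 1L]] <- data.frame(
          V = vs[i], P = pressure, t = comp$centroid[k],
          sigma = comp$sigma[k], area = comp$area[k],
          frac = comp$area[k] / sum(comp$area))
      }
    }
    fams[[k]] <- do.call(rbind, rows)
  }
  keep <- vapply(fams, function(f) !is.null(f) && nrow(f) >= 2L, logical(1))
  if (any(!keep))
    warning(sum(!keep), " family(ies) dropped: fewer than 2 voltage points")
  fams[keep]
}

#' Complete a conformer family: regression, CCS and abundance
#'
#' Runs the arrival-time vs P/V regression on the family's points, converts
#' the reduced mobility to a collision cross section, propagates the fit
#' standard error, and sets the abundance to the mean within-voltage area
#' fraction.
#'
#' @param family a family skeleton from \code{\link{trackFamilies}}
#' @param z charge of the species
#' @param ionMass ion mass in u (n * monomer mass + z protons)
#' @param instrument an \linkS4class{InstrumentConfig}
#' @param rank family rank (1 = earliest-arriving)
#' @return A \linkS4class{ConformerFamily}.
#' @export
familyCCS <- function(family, z, ionMass, instrument, rank = 1L) {
  if (nrow(family) < 2L) stop("family needs >= 2 points")
  fit <- mobilityRegression(family[, c("P", "V", "t")], instrument)
  mu <- reducedMass(ionMass, instrument@bufferGasMass)
  om <- ccsFromReducedMobility(fit@K0, z, instrument@temperature, mu)
  omErr <- om * fit@K0Stderr / fit@K0  # Omega is proportional to 1/K0
  new("ConformerFamily", ccs = om, ccsStderr = omErr,
      abundance = mean(family$frac), rank = as.integer(rank),
      perVoltageCentroids = family, fit = fit)
}

#' Full per-species analysis of an ATD bundle
#'
#' Deconvolves the trace at every voltage, tracks components into families
#' by rank, and completes each family with its mobility regression, CCS and
#' abundance (renormalised over the retained families).
#'
#' @param atd an \linkS4class{ATDSet}
#' @param z charge of the species the bundle was selected on
#' @param ionMass ion mass in u
#' @param kMax maximum components per trace
#' @param minSnr detection threshold (units of baseline MAD)
#' @return List of \linkS4class{ConformerFamily}, ordered by rank.
#' @examples
#' tr <- groundTruth(ionSpecies(2, 7),
#'                   data.frame(ccs = c(1217, 1701), abundance = c(0.8, 0.2)))
#' atd <- simulateATDSet(tr, instrumentConfig())
#' atdFamilies(atd, z = 7, ionMass = 2 * 5733.55 + 7)
#' @export
atdFamilies <- function(atd, z, ionMass, kMax = 4L, minSnr = 3) {
  perVoltage <- list()
  for (tr in atd@traces) {
    comp <- deconvolveATD(tr, kMax = kMax, minSnr = minSnr)
    perVoltage[[as.character(tr$V)]] <- comp
  }
  pressure <- atd@traces[[1]]$P
  fams <- trackFamilies(perVoltage, pressure)
  out <- lapply(seq_along(fams), function(k)
    familyCCS(fams[[k]], z, ionMass, atd@instrument, rank = k))
  tot <- sum(vapply(out, abundance, numeric(1)))
  if (tot > 0)
    out <- lapply(out, function(f) { f@abundance <- f@abundance / tot; f })
  out
}

#' Composite CCS distribution across charge states
#'
#' Pools the conformer families of all charge states of each oligomer order
#' into one weighted-Gaussian distribution on the CCS axis (the composite
#' view of the conformational populations): each family becomes a Gaussian
#' at its CCS with sd = max(ccs stderr, 1 percent of CCS), and weights are
#' renormalised within the oligomer order.
#'
#' @param assignments data.frame with columns \code{n}, \code{ccs},
#'   \code{ccs_stderr}, \code{abundance} (one row per family), or a list of
#'   \code{list(n =, family = ConformerFamily)} pairs
#' @param defaultWidthFrac fallback sd as a fraction of CCS
#' @return List keyed by oligomer order; each entry a data.frame with
#'   columns mean, sd, weight (weights summing to 1).
#' @export
compositeDistribution <- function(assignments, defaultWidthFrac = 0.01) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    assignments <- do.call(rbind, lapply(assignments, function(a)
      data.frame(n = a$n, ccs = a$family@ccs,
                 ccs_stderr = a$family@ccsStderr,
                 abundance = a$family@abundance)))
  }
  stopifnot(nrow(assignments) >= 1L)
  out <- list()
  for (n in sort(unique(assignments$n))) {
    rows <- assignments[assignments$n == n, ]
    sd <- pmax(rows$ccs_stderr, defaultWidthFrac * rows$ccs)
    w <- rows$abundance / sum(rows$abundance)
    out[[as.character(n)]] <- data.frame(mean = rows$ccs, sd = sd,
                                         weight = w)
  }
  out
}
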