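# Structure-side metrics: Rg, projection-approximation CCS, Kabsch RMSD,
# the Rg-CCS calibration, the quartile statistic and the cuboid Rg.

test_that("radius of gyration matches analytic cases", {
  expect_equal(radiusOfGyration(
    structureModel(rbind(c(-1, 0, 0), c(1, 0, 0)), mass = 1)), 1.0)
  expect_equal(radiusOfGyration(structureModel(matrix(0, 1, 3))), 0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radiusOfGyration(structureModel(cube, mass = 1)), sqrt(3))
  # rigid motion invariance
  set.seed(2)
  pts <- matrix(rnorm(30), ncol = 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m1 <- structureModel(pts, mass = 1:10)
  m2 <- structureModel(pts %*% t(R) + 5, mass = 1:10)
  expect_equal(radiusOfGyration(m2), radiusOfGyration(m1), tolerance = 1e-12)
})

test_that("PA CCS reproduces the analytic sphere and the no-overlap limit", {
  one <- structureModel(matrix(0, 1, 3), radius = 1)
  pa <- paCCS(one, probeRadius = 1, nOrientations = 100, gridStep = 0.01)
  expect_equal(pa$ccs, pi * 4, tolerance = 2e-4)
  expect_equal(pa$stderr, 0, tolerance = 1e-9)
  two <- structureModel(rbind(c(0, 0, 0), c(500, 0, 0)), radius = 1)
  pa2 <- paCCS(two, probeRadius = 1, nOrientations = 100, gridStep = 0.01)
  expect_equal(pa2$ccs, 2 * pi * 4, tolerance = 1e-3)
})

test_that("PA CCS matches a pixel-rasterisation oracle on an overlapping chain", {
  chain <- structureModel(cbind(seq(0, 9), 0, 0), radius = 1.5)
  n <- 100L; seed <- 4L
  pa <- paCCS(chain, probeRadius = 1, nOrientations = n, seed = seed,
              gridStep = 0.05)
  # independent oracle: 2-D pixel-centre rasterisation on the same rotations
  set.seed(seed)
  rots <- dtims:::.randomRotations(n)
  r <- chain@radius + 1
  px <- 0.05
  areas <- vapply(rots, function(R) {
    p <- chain@xyz %*% t(R)
    xs <- seq(min(p[, 1] - r) - px, max(p[, 1] + r) + px, by = px)
    ys <- seq(min(p[, 2] - r) - px, max(p[, 2] + r) + px, by = px)
    g <- expand.grid(x = xs, y = ys)
    inside <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(p)))
      inside <- inside | ((g$x - p[i, 1])^2 + (g$y - p[i, 2])^2 < r[i]^2)
    sum(inside) * px^2
  }, numeric(1))
  expect_equal(pa$ccs, mean(areas), tolerance = 0.01)
})

test_that("PA CCS is rigid-motion invariant and scales as s^2", {
  set.seed(9)
  pts <- matrix(rnorm(24, sd = 3), ncol = 3)
  m <- structureModel(pts, radius = 1.6)
  base <- paCCS(m, nOrientations = 400, seed = 1)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- structureModel(pts %*% t(R) + 10, radius = 1.6)
  got <- paCCS(rot, nOrientations = 400, seed = 2)
  expect_equal(got$ccs, base$ccs,
               tolerance = 5 * (base$stderr + got$stderr) / base$ccs)
  s <- 1.7
  scaled <- structureModel(pts * s, radius = 1.6 * s)
  sc <- paCCS(scaled, probeRadius = s, nOrientations = 400, seed = 3)
  baseP <- paCCS(m, probeRadius = 1, nOrientations = 400, seed = 3)
  expect_equal(sc$ccs, s^2 * baseP$ccs,
               tolerance = 5 * (sc$stderr / sc$ccs + baseP$stderr / baseP$ccs))
})

test_that("PA Monte-Carlo standard error shrinks as 1/sqrt(n)", {
  set.seed(3)
  m <- structureModel(matrix(rnorm(30, sd = 4), ncol = 3), radius = 1.5)
  se100 <- paCCS(m, nOrientations = 100, seed = 5)$stderr
  se1000 <- paCCS(m, nOrientations = 1000, seed = 5)$stderr
  ratio <- se100 / se1000
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
})

test_that("Kabsch RMSD is zero under rigid motion and minimal vs brute force", {
  set.seed(7)
  A <- matrix(rnorm(12), ncol = 3)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mA <- structureModel(A)
  expect_equal(kabschRMSD(mA, mA), 0, tolerance = 1e-12)
  mB <- structureModel(A %*% t(R) + 3)
  expect_equal(kabschRMSD(mA, mB), 0, tolerance = 1e-9)
  # independent oracle: numerical minimisation over quaternions
  B <- A + matrix(rnorm(12, sd = 0.3), ncol = 3)
  mBd <- structureModel(B)
  got <- kabschRMSD(mA, mBd)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  rmsdOf <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    sqrt(mean(rowSums((Bc - Ac %*% t(R))^2)))
  }
  set.seed(21)
  starts <- matrix(rnorm(4 * 50), ncol = 4)
  best <- min(apply(starts, 1, function(q)
    optim(q, rmsdOf, method = "Nelder-Mead",
          control = list(reltol = 1e-14, maxit = 2000))$value))
  expect_equal(got, best, tolerance = 1e-4)
  expect_lte(got, best + 1e-6)
  expect_error(kabschRMSD(mA, structureModel(matrix(0, 2, 3))), "differ")
})

test_that("Rg-CCS regression is exact on a line and tight on sphere ensembles", {
  exact <- rgCcsRegression(data.frame(rg = 1:5, ccs = 10 + 3 * (1:5)))
  expect_equal(exact$slope, 3); expect_equal(exact$intercept, 10)
  expect_equal(exact$pearson_r, 1)
  expect_equal(exact$predict(10), 40)
  # conformer ensemble emulated by scaled compact clusters: PA CCS grows
  # quadratically over a narrow size range, hence near-linear in Rg
  set.seed(13)
  base <- matrix(rnorm(45, sd = 2.5), ncol = 3)
  pairs <- do.call(rbind, lapply(seq(1, 1.6, length.out = 8), function(s) {
    m <- structureModel(base * s, radius = 1.7)
    data.frame(rg = radiusOfGyration(m),
               ccs = paCCS(m, nOrientations = 150, seed = 17)$ccs)
  }))
  fit <- rgCcsRegression(pairs)
  expect_gte(fit$pearson_r, 0.99)
  expect_error(rgCcsRegression(data.frame(rg = c(2, 2), ccs = c(1, 2))),
               "distinct")
})

test_that("slope recovery under 5% noise is unbiased within 10%", {
  set.seed(31)
  slopes <- replicate(100, {
    rg <- seq(10, 22, length.out = 12)
    ccsTrue <- 200 + 55 * rg
    ccsNoisy <- ccsTrue * (1 + rnorm(12, sd = 0.05))
    rgCcsRegression(data.frame(rg = rg, ccs = ccsNoisy))$slope
  })
  expect_equal(mean(slopes), 55, tolerance = 0.10)
})

test_that("quartile response splits compact to extended", {
  q <- quartileResponse(10:17, c(8, 8, 6, 6, 4, 4, 2, 2))
  expect_equal(unname(q$means), c(8, 6, 4, 2))
  expect_equal(unname(q$sizes), rep(2L, 4))
  # constant response -> equal means; sizes differ by at most one
  q2 <- quartileResponse(rnorm(11), rep(3, 11))
  expect_equal(unname(q2$means), rep(3, 4))
  expect_lte(diff(range(q2$sizes)), 1)
  # negatively correlated ensemble: strictly decreasing quartile means,
  # the qualitative beta-content pattern
  set.seed(8)
  rg <- runif(200, 10, 22)
  beta <- 25 - rg + rnorm(200, sd = 0.5)
  q3 <- quartileResponse(rg, beta)
  expect_true(all(diff(q3$means) < 0))
  expect_error(quartileResponse(1:5, 1:4), "mismatch")
})

test_that("cuboid Rg covers the analytic limits", {
  expect_equal(cuboidRg(2, 2, 2), 1)            # cube: a/2
  expect_equal(cuboidRg(30, 40, 0), sqrt(2500 / 12))
  expect_equal(cuboidRg(30, 40, 0), 14.43, tolerance = 1e-3)
  expect_equal(cuboidRg(6, 0, 0), 6 / sqrt(12)) # rod limit
  expect_error(cuboidRg(0, 0, 0), ">= 0")
})

test_that("PDB files load into structure models", {
  # minimal synthetic PDB written on the fly
  pdb <- file.path(tempdir(), "toy.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), pdb)
  m <- readPDBModel(pdb)
  expect_equal(nrow(m@xyz), 4)
  expect_equal(m@element, c("N", "C", "C", "O"))
  expect_gt(radiusOfGyration(m), 0)
  unlink(pdb)
})
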