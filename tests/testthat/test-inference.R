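# Posterior evaluation: noise estimation, energy, profiling of the
# totals, Laplace marginalization, priors, total posterior and the grid.

test_that("noise estimates are per-sample, per-channel SDs with a floor", {
  dn <- matrix(c(9, 10, 11), 3, 1)
  same <- matrix(10, 3, 1)
  fs <- FretSet(donor = dn, acceptor = same, fret = dn + 1)
  s <- estimateNoise(fs)
  expect_equal(s[1, "donor"], 1.0)      # sd of (9,10,11), ddof = 1
  expect_equal(s[1, "fret"], 1.0)
  expect_equal(s[1, "acceptor"], 1e-12 * 11)  # identical replicates: floor

  one <- FretSet(donor = matrix(1, 1, 1), acceptor = matrix(1, 1, 1),
                 fret = matrix(1, 1, 1))
  expect_error(estimateNoise(one), "explicit 'sigma'")
  expect_equal(unname(estimateNoise(one, sigma = c(1, 2, 3))[1, ]),
               c(1, 2, 3))

  # reference-study data: sigma/mean close to the generating r
  fs2 <- refStudyData(seed = 21, n = 50)
  s2 <- estimateNoise(fs2)
  mns <- vapply(c("donor", "acceptor", "fret"),
                function(ch) colMeans(assay(fs2, ch)), numeric(3))
  expect_true(all(abs(s2 / mns - 0.05) < 0.02))
})

test_that("sample energy equals the sum of scalar normal log-densities", {
  fs <- refStudyData(seed = 13, n = 6)
  kt <- defaultKappa()
  sig <- estimateNoise(fs)
  for (j in 1:3) {
    D0 <- 1.3e-6; A0 <- 0.8e-6
    e <- sampleEnergy(fs, j, D0, A0, 1e-6, 0.4, kt)
    mu <- predictIntensities(D0, A0, 1e-6, 0.4, kt)
    oracle <- 0
    for (k in 1:3) {
      x <- assay(fs, c("donor", "acceptor", "fret")[k])[, j]
      oracle <- oracle - sum(dnorm(x, mu[k], sig[j, k], log = TRUE))
    }
    expect_equal(e, oracle, tolerance = 1e-10)
  }
})

test_that("perfect fit leaves only the normalization term", {
  kt <- defaultKappa()
  fs <- simulateFretData(1e-6, 0.4, 1e-6, 1e-6, n = 5, r = 0, seed = 2)
  sig <- c(1e-8, 2e-8, 3e-8)
  e1 <- sampleEnergy(fs, 1, 1e-6, 1e-6, 1e-6, 0.4, kt, noise = sig)
  expect_equal(e1, 5 * sum(log(sig * sqrt(2 * pi))), tolerance = 1e-9)
  # doubling every sigma at the perfect fit adds (replicates x 3) log 2
  e2 <- sampleEnergy(fs, 1, 1e-6, 1e-6, 1e-6, 0.4, kt, noise = 2 * sig)
  expect_equal(e2 - e1, 5 * 3 * log(2), tolerance = 1e-9)
})

test_that("profiling the totals recovers generating values", {
  kt <- defaultKappa()
  # linear case (E_fr = 0): unique quadratic minimum at the truth
  fs0 <- simulateFretData(1e-6, 0, 2e-6, 0.5e-6, n = 4, r = 0, seed = 4)
  pf <- profileTotals(fs0, 1, 1e-6, 0, kt, noise = c(1e-9, 1e-9, 1e-9))
  expect_equal(pf$D0star, 2e-6, tolerance = 1e-5)
  expect_equal(pf$A0star, 0.5e-6, tolerance = 1e-5)

  # nonlinear case evaluated at the generating (Kd, E_fr)
  fs <- simulateFretData(1e-6, 0.4, 1e-6, 1e-6, n = 4, r = 0, seed = 4)
  pf <- profileTotals(fs, 1, 1e-6, 0.4, kt, noise = c(1e-9, 1e-9, 1e-9))
  expect_equal(pf$D0star, 1e-6, tolerance = 1e-4)
  expect_equal(pf$A0star, 1e-6, tolerance = 1e-4)

  # all-zero data pins the totals at zero
  z <- matrix(0, 3, 1)
  fz <- FretSet(donor = z, acceptor = z, fret = z)
  pf <- profileTotals(fz, 1, 1e-6, 0.4, kt, noise = c(1, 1, 1))
  expect_equal(pf$D0star, 0)
  expect_equal(pf$A0star, 0)
})

test_that("Laplace marginal matches brute-force quadrature", {
  kt <- defaultKappa()
  # E_fr = 0: energy exactly quadratic, Laplace is exact
  fs0 <- simulateFretData(1e-6, 0, 1e-6, 1e-6, n = 6, r = 0.05, seed = 8)
  lap <- laplaceLogMarginal(fs0, 1, 1e-6, 0, kt)
  expect_true(lap@valid)
  expect_equal(lap@logMarginal,
               -lap@Emin + log(2 * pi) -
                 0.5 * log(det(lap@hessian)), tolerance = 1e-12)
  quad <- quadLogMarginal(fs0, 1, 1e-6, 0, kt)
  expect_lt(abs(lap@logMarginal - quad), 1e-6)

  # randomized E_fr > 0 cases stay within 0.05 log units
  set.seed(31)
  for (i in 1:4) {
    efr <- runif(1, 0.2, 0.8)
    kd <- 10^runif(1, -7, -5)
    fs <- simulateFretData(kd, efr, 10^runif(1, -6.5, -5.5),
                           10^runif(1, -6.5, -5.5), n = 6,
                           r = runif(1, 0.02, 0.1), seed = 100 + i)
    lap <- laplaceLogMarginal(fs, 1, kd, efr, kt)
    quad <- quadLogMarginal(fs, 1, kd, efr, kt)
    expect_lt(abs(lap@logMarginal - quad), 0.05)
  }
})

test_that("marginal is invariant under replicate permutation", {
  fs <- refStudyData(seed = 17, n = 8)
  kt <- defaultKappa()
  l1 <- laplaceLogMarginal(fs, 2, 1e-6, 0.4, kt)
  dn <- assay(fs, "donor"); ac <- assay(fs, "acceptor")
  fr <- assay(fs, "fret")
  p <- c(5, 3, 8, 1, 7, 2, 6, 4)
  fsP <- FretSet(donor = dn[p, ], acceptor = ac[p, ], fret = fr[p, ],
                 sampleData = as.data.frame(
                   SummarizedExperiment::colData(fs))[, c("D0", "A0")])
  l2 <- laplaceLogMarginal(fsP, 2, 1e-6, 0.4, kt)
  expect_equal(l1@logMarginal, l2@logMarginal, tolerance = 1e-9)
})

test_that("priors: uniform constant, truncated Gaussian, support edges", {
  pu <- fretPrior()
  expect_equal(logPrior(-6, 0.3, pu), logPrior(-8, 0.9, pu))
  expect_identical(logPrior(-13, 0.5, pu), -Inf)   # outside Kd bounds
  expect_identical(logPrior(-6, 1.2, pu), -Inf)    # efficiency > 1

  pg <- fretPrior(efr = c(0.45, 0.15))
  gap <- logPrior(-6, 0.45, pg) - logPrior(-6, 0.30, pg)
  expect_equal(gap, dnorm(0.45, 0.45, 0.15, log = TRUE) -
                 dnorm(0.30, 0.45, 0.15, log = TRUE), tolerance = 1e-12)
  expect_gt(gap, 0)

  # normalization over the support
  dens <- integrate(function(x)
    exp(vapply(x, function(xx) logPrior(-6, xx, pg), numeric(1))),
    0, 1)$value
  width <- diff(pu@kdBounds)
  expect_equal(dens * width, 1, tolerance = 1e-6)
})

test_that("log posterior composes prior and per-sample marginals", {
  kt <- defaultKappa()
  fs1 <- simulateFretData(1e-6, 0.4, 1e-6, 1e-6, n = 5, r = 0.05, seed = 6)
  pu <- fretPrior()
  lap <- laplaceLogMarginal(fs1, 1, 1e-6, 0.4, kt)
  lp <- logPosterior(fs1, 1e-6, 0.4, kt, pu)
  expect_equal(lp, logPrior(-6, 0.4, pu) + lap@logMarginal,
               tolerance = 1e-9)

  # duplicating the sample doubles the likelihood term exactly
  dn <- assay(fs1, "donor")
  fs2 <- FretSet(donor = cbind(dn, dn),
                 acceptor = cbind(assay(fs1, "acceptor"),
                                  assay(fs1, "acceptor")),
                 fret = cbind(assay(fs1, "fret"), assay(fs1, "fret")))
  lp2 <- logPosterior(fs2, 1e-6, 0.4, kt, pu)
  expect_equal(lp2 - logPrior(-6, 0.4, pu),
               2 * (lp - logPrior(-6, 0.4, pu)), tolerance = 1e-8)

  # truth beats a far-off Kd on the study dataset
  fs <- refStudyData(seed = 7)
  expect_gt(logPosterior(fs, 1e-6, 0.4, kt),
            logPosterior(fs, 1e-4, 0.4, kt))
})

test_that("energy grid: argmin near truth, flat ridge at zero efficiency", {
  fs <- refStudyData(seed = 19)
  kt <- defaultKappa()
  kdg <- seq(-8, -4, by = 0.25)
  efg <- seq(0.05, 0.95, by = 0.05)
  g <- energyGrid(fs, kdg, efg, kt)
  idx <- arrayInd(which.min(g), dim(g))
  expect_lt(abs(kdg[idx[1]] - (-6)), 0.5)
  expect_lt(abs(efg[idx[2]] - 0.4), 0.1)

  # a 1 x 1 grid is a single posterior evaluation
  g1 <- energyGrid(fs, -6, 0.4, kt)
  expect_equal(g1[1, 1], -logPosterior(fs, 1e-6, 0.4, kt),
               tolerance = 1e-8)

  # with E_fr = 0 the predictions are Kd-free: constant energy row
  g0 <- energyGrid(fs, seq(-9, -3, by = 1), 0, kt)
  expect_lt(max(g0) - min(g0), 1e-6 * max(1, abs(mean(g0))))
})
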