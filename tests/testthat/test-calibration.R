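# Calibration of the kappa constants from donor-only, acceptor-only and
# tandem-construct blocks.

test_that("absolute calibration divides channel means by concentration", {
  kt <- defaultKappa()
  cs <- simulateCalibrationData(kt, efrConstruct = 0.35, cD = 1e-6,
                                cA = 2e-6, n = 5, r = 0, seed = 1)
  res <- calibrateAbsolute(cs, c(donor_only = 1e-6, acceptor_only = 2e-6))
  expect_equal(unname(kappaD(res@kappa)), unname(kappaD(kt)),
               tolerance = 1e-10)
  expect_equal(unname(kappaA(res@kappa)), unname(kappaA(kt)),
               tolerance = 1e-10)
  expect_equal(res@mode, "absolute")

  # noisy round-trip: recovered constants within 3 propagated SEs
  cs2 <- simulateCalibrationData(kt, 0.35, cD = 1e-6, cA = 2e-6, n = 50,
                                 r = 0.05, seed = 2)
  res2 <- calibrateAbsolute(cs2, c(donor_only = 1e-6, acceptor_only = 2e-6))
  expect_true(all(abs(kappaD(res2@kappa) - kappaD(kt)) <=
                    3 * res2@se$kappa_D + 1e-12))
  expect_true(all(abs(kappaA(res2@kappa) - kappaA(kt)) <=
                    3 * res2@se$kappa_A + 1e-12))

  # an all-zero block gives zero constants with zero spread
  zd <- simulateCalibrationData(kt, 0.35, cD = 1e-6, cA = 2e-6, n = 4,
                                r = 0, seed = 3)
  dn <- assay(zd, "donor"); ac <- assay(zd, "acceptor")
  fr <- assay(zd, "fret")
  dn[, "donor_only"] <- ac[, "donor_only"] <- fr[, "donor_only"] <- 0
  fz <- FretSet(donor = dn, acceptor = ac, fret = fr)
  rz <- calibrateAbsolute(fz, c(donor_only = 1e-6, acceptor_only = 2e-6))
  expect_equal(unname(kappaD(rz@kappa)), rep(0, 3))
  expect_equal(rz@se$kappa_D, rep(0, 3))
  expect_error(calibrateAbsolute(fz, c(donor_only = 0,
                                       acceptor_only = 1e-6)), "positive")
})

test_that("extinction-ratio rule ties FRET constants to acceptor ones", {
  kt <- defaultKappa()
  expect_equal(fretKappaFromExtinction(c(1, 2, 3), c(1, 1, 1)), c(1, 2, 3))
  expect_equal(fretKappaFromExtinction(c(1, 2, 3), c(20, 0.1, 20)),
               c(20, 0.2, 60))
  kt2 <- fretKappaFromExtinction(kt, c(2, 0.5, 3))
  expect_equal(unname(kappaF(kt2)), unname(kappaA(kt) * c(2, 0.5, 3)))
  expect_error(fretKappaFromExtinction(c(1, 2, 3), c(1, -1, 1)), "positive")

  # round trip: generate kappa_F from a known ratio, re-derive it
  ratio <- c(1.5, 0.2, 4)
  ktGen <- KappaTable(kappaD(kt), kappaA(kt), kappaA(kt) * ratio)
  expect_equal(unname(kappaF(fretKappaFromExtinction(ktGen, ratio))),
               unname(kappaF(ktGen)))
})

# relative-gauge gear: generating constants scaled to kappa_D[1] = 1 so
# candidate tables are in the gauge the calibration posterior requires
gaugeKappa <- function(kt) {
  s <- kappaD(kt)[1]
  KappaTable(kappaD(kt) / s, kappaA(kt) / s, kappaF(kt) / s)
}

test_that("calibration posterior peaks at the generating constants", {
  kt <- gaugeKappa(defaultKappa())
  cs <- simulateCalibrationData(kt, efrConstruct = 0.35, n = 10, r = 0.01,
                                seed = 3)
  atTruth <- calibLogPosterior(cs, kt, 0.35)
  for (mutate in 1:3) {
    k2 <- kt@kappa
    k2[mutate, "A"] <- 2 * k2[mutate, "A"] + 0.01
    ktBad <- KappaTable(k2[, "D"], k2[, "A"], k2[, "F"])
    expect_gt(atTruth, calibLogPosterior(cs, ktBad, 0.35))
  }
  expect_gt(atTruth, calibLogPosterior(cs, kt, 0.8))
  expect_identical(calibLogPosterior(cs, kt, 1.4), -Inf)
  offGauge <- KappaTable(2 * kappaD(kt), kappaA(kt), kappaF(kt))
  expect_error(calibLogPosterior(cs, offGauge, 0.35), "gauge")
})

test_that("gauge invariance: rescaled constants and inverted concentrations
          give identical data and identical posterior", {
  kt <- defaultKappa()
  c0 <- 3.7
  ktScaled <- KappaTable(kappaD(kt) * c0, kappaA(kt) * c0, kappaF(kt) * c0)
  a <- simulateCalibrationData(kt, 0.35, cD = 1e-6, cA = 2e-6, cDA = 5e-7,
                               n = 8, r = 0.03, seed = 4)
  b <- simulateCalibrationData(ktScaled, 0.35, cD = 1e-6 / c0,
                               cA = 2e-6 / c0, cDA = 5e-7 / c0,
                               n = 8, r = 0.03, seed = 4)
  for (ch in c("donor", "acceptor", "fret"))
    expect_equal(assay(a, ch), assay(b, ch), tolerance = 1e-12)
  cand <- gaugeKappa(kt)
  expect_equal(calibLogPosterior(a, cand, 0.35),
               calibLogPosterior(b, cand, 0.35), tolerance = 1e-9)
})

test_that("block concentration marginal agrees with 1-D quadrature", {
  kt <- gaugeKappa(defaultKappa())
  cs <- simulateCalibrationData(kt, 0.35, cD = 1e-6, n = 6, r = 0.05,
                                seed = 5)
  stat <- fretBayes:::.blockStats(cs, "donor_only")
  g <- kappaD(kt)
  ml <- fretBayes:::.calibBlockML(stat, g, "shared")
  # quadrature of (1/2) Gamma(N/2) pi^(-N/2) S(c)^(-N/2) over c
  n <- stat[1]; N <- 3 * n
  m <- stat[2:4]; ssq0 <- stat[5:7]
  S <- function(c) vapply(c, function(ci)
    sum(ssq0 + n * (m - g * ci)^2), numeric(1))
  cs0 <- sum(g * m) / sum(g^2)
  const <- lgamma(N / 2) - log(2) - (N / 2) * log(pi)
  # analytic curvature (independent of the package FD route) locates the
  # integration window around the narrow concentration spike
  sdC <- 1 / sqrt(N * n * sum(g^2) / S(cs0))
  quad <- integrate(function(c) exp(-(N / 2) * (log(S(c)) - log(S(cs0)))),
                    max(cs0 - 12 * sdC, 0), cs0 + 12 * sdC,
                    rel.tol = 1e-10)$value
  mlQuad <- const - (N / 2) * log(S(cs0)) + log(quad)
  expect_lt(abs(ml - mlQuad), 0.01 * abs(mlQuad))
})

test_that("relative calibration recovers the kappa ratios and construct
          efficiency by MCMC", {
  ratio <- unname(kappaF(defaultKappa()) / kappaA(defaultKappa()))
  ktTrue <- gaugeKappa(defaultKappa())
  cs <- simulateCalibrationData(ktTrue, efrConstruct = 0.35, cD = 1e-6,
                                cA = 1.5e-6, cDA = 8e-7, n = 20, r = 0.01,
                                seed = 6)
  res <- calibrateRelative(cs, ratio, nSteps = 4000, seed = 6)
  expect_equal(res@kappa@kappa[1, "D"], 1)
  expect_equal(unname(kappaD(res@kappa)), unname(kappaD(ktTrue)),
               tolerance = 0.05)
  expect_equal(unname(kappaA(res@kappa)), unname(kappaA(ktTrue)),
               tolerance = 0.05)
  expect_equal(res@efrConstruct, 0.35, tolerance = 0.05)
  expect_equal(res@mode, "relative")

  # without the construct block the FRET constants are unidentifiable
  keep <- c("donor_only", "acceptor_only")
  cs2 <- FretSet(donor = assay(cs, "donor")[, keep],
                 acceptor = assay(cs, "acceptor")[, keep],
                 fret = assay(cs, "fret")[, keep])
  expect_error(calibrateRelative(cs2, ratio), "construct")
})

test_that("credible intervals from repeated calibrations cover the truth", {
  ratio <- unname(kappaF(defaultKappa()) / kappaA(defaultKappa()))
  ktTrue <- gaugeKappa(defaultKappa())
  trueVals <- c(kappaD(ktTrue)[2:3], kappaA(ktTrue), 0.35)
  nRep <- 8
  hits <- 0
  total <- 0
  for (rep in seq_len(nRep)) {
    cs <- simulateCalibrationData(ktTrue, 0.35, cD = 1e-6, cA = 1.5e-6,
                                  cDA = 8e-7, n = 20, r = 0.03,
                                  seed = 100 + rep)
    res <- calibrateRelative(cs, ratio, nSteps = 6000, seed = 100 + rep)
    nat <- res@draws
    for (p in 1:6) {
      ci <- quantile(nat[, p], c(0.025, 0.975))
      total <- total + 1
      if (trueVals[p] >= ci[1] && trueVals[p] <= ci[2]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.85)
})
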