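# Metropolis-Hastings machinery: core walk, tuning, burn-in detection,
# convergence checks, posterior summaries.

# assemble a FretChains object from raw draw matrices (for summary and
# convergence tests that bypass the FRET likelihood)
makeChains <- function(..., burn = 1L) {
  states <- lapply(list(...), function(m) {
    colnames(m) <- c("log10_kd", "efr")
    m
  })
  new("FretChains", states = states,
      energies = lapply(states, function(s) rep(0, nrow(s))),
      accepted = lapply(states, function(s) c(NA, rep(TRUE, nrow(s) - 1))),
      burnIn = rep(as.integer(burn), length(states)),
      proposal = proposalSpec(0.1, 0.1),
      seeds = seq_along(states))
}

test_that("flat target accepts every proposal and walks freely", {
  res <- fretBayes:::.mhChain(function(x) 0, c(0, 0), 2000, c(0.3, 0.1),
                              seed = 5)
  expect_true(all(res$accepted[-1]))
  steps <- diff(res$states)
  expect_equal(sd(steps[, 1]), 0.3, tolerance = 0.1)
  expect_equal(sd(steps[, 2]), 0.1, tolerance = 0.1)
})

test_that("sampler reproduces an injected 2-D Gaussian target", {
  mu <- c(1, -2); s <- c(2, 0.5)
  logpost <- function(x) sum(dnorm(x, mu, s, log = TRUE))
  res <- fretBayes:::.mhChain(logpost, mu, 50000, 2.4 * s, seed = 42)
  draws <- res$states[-(1:500), ]
  expect_equal(colMeans(draws), mu, tolerance = 0.12)
  expect_equal(apply(draws, 2, sd), s, tolerance = 0.1)
  expect_lt(abs(cor(draws[, 1], draws[, 2])), 0.1)
  # acceptance flags agree with state repeats
  rep1 <- res$states[-1, 1] == res$states[-nrow(res$states), 1]
  expect_equal(!res$accepted[-1], rep1)
})

test_that("chains demand a finite starting posterior", {
  fs <- refStudyData(seed = 3)
  expect_error(runChain(fs, defaultKappa(), fretPrior(), c(-20, 0.4),
                        100, proposalSpec(0.1, 0.05)), "-Inf")
})

test_that("step tuning shrinks oversized steps into the acceptance band", {
  fs <- refStudyData(seed = 23)
  prop <- tuneStepSize(fs, defaultKappa(), fretPrior(), c(-6, 0.4),
                       seed = 2, initialStep = c(4, 0.4))
  expect_lt(prop@stepLogKd, 4)
  expect_lt(prop@stepEfr, 0.4)
  acc <- attr(prop, "acceptance")
  expect_gte(acc, 0.40)
  expect_lte(acc, 0.60)

  # flat target: any step accepts everything; tuner warns and returns
  expect_warning(
    fretBayes:::.tuneSteps(function(x) 0, c(0, 0), c(1, 1), seed = 1,
                           maxBlocks = 5, stepCap = c(10, 10)),
    "unreachable|band")
})

test_that("burn-in detection finds the stationary segment", {
  set.seed(8)
  # already stationary: index within one window
  e <- rnorm(1000, 100, 1)
  expect_lte(detectBurnIn(e), 100)

  # prepended high-energy block pushes the index past it
  e2 <- c(rnorm(250, 500, 1), rnorm(750, 100, 1))
  idx <- detectBurnIn(e2)
  expect_gt(idx, 150)
  expect_lte(idx, 500)

  # staircase chain that only settles late: capped at half with warning
  e3 <- c(rep(300, 150), rep(200, 150), rep(100, 100)) + rnorm(400, 0, 1e-3)
  expect_warning(idx3 <- detectBurnIn(e3), "half")
  expect_equal(idx3, 200L)
  expect_error(detectBurnIn(rnorm(150)), "too short")
})

test_that("PSRF is 1 for identical chains and large for disjoint ones", {
  set.seed(10)
  m <- cbind(rnorm(500, -6, 0.2), rnorm(500, 0.4, 0.05))
  same <- checkConvergence(makeChains(m, m, m))
  expect_equal(unname(same$psrf), c(1, 1))
  expect_true(same$pass)

  far <- cbind(rnorm(500, -9, 0.1), rnorm(500, 0.1, 0.02))
  bad <- checkConvergence(makeChains(m, far))
  expect_gt(max(bad$psrf), 1.1)
  expect_false(bad$pass)
  expect_error(checkConvergence(makeChains(m)), "2 chains")
})

test_that("posterior summaries: scales, cv arithmetic, error metric", {
  truth <- list(Kd = 1e-6, efr = 0.4)
  # all draws at truth: zero error, zero cv
  m <- cbind(rep(log10(truth$Kd), 50), rep(truth$efr, 50))
  s <- summarizePosterior(makeChains(m), truth = truth)
  expect_equal(s["Kd", "error"], 0)
  expect_equal(s["Kd", "cv"], 0)
  expect_equal(s["E_fr", "error"], 0)

  # draws at 0.5x and 1.5x truth: mean on the natural scale is the truth,
  # so the log-ratio error is 0 and the cv is 0.5
  m2 <- cbind(log10(c(0.5, 1.5) * truth$Kd), c(0.4, 0.4))
  s2 <- summarizePosterior(makeChains(m2), truth = truth)
  expect_equal(s2["Kd", "mean"], truth$Kd)
  expect_equal(s2["Kd", "error"], 0)
  expect_equal(s2["Kd", "cv"], 0.5)
  # percentiles ordered
  expect_true(all(diff(unlist(s2["Kd", c("q05", "q50", "q95")])) >= 0))
})

test_that("acceptance rates come from the recorded flags", {
  fs <- refStudyData(seed = 29)
  ch <- runChain(fs, defaultKappa(), fretPrior(), c(-6, 0.4), 400,
                 proposalSpec(0.15, 0.02), seed = 3)
  a <- acceptanceRate(ch)
  expect_gte(a, 0)
  expect_lte(a, 1)
  st <- chainStates(ch)[[1]]
  acc <- ch@accepted[[1]]
  repeated <- st[-1, 1] == st[-nrow(st), 1] & st[-1, 2] == st[-nrow(st), 2]
  expect_equal(!acc[-1], unname(repeated))
})
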