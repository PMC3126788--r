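suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately implemented with different numerics than the package
# (bisection instead of the closed-form root, nested quadrature instead
# of the Laplace identity).

# bisection root of (D0 - DA)(A0 - DA) - Kd * DA = 0 on [0, min(D0, A0)];
# iterated to floating-point exhaustion so the oracle is limited only by
# double precision
eqOracle <- function(D0, A0, Kd) {
  f <- function(DA) (D0 - DA) * (A0 - DA) - Kd * DA
  lo <- 0
  hi <- min(D0, A0)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force 2-D quadrature of the marginal likelihood of one sample:
# integrate exp(-energy(D0, A0)) over a box spanning many posterior SDs
# around the profiled optimum. The energy is rebuilt here from the raw
# replicates as a plain sum of Gaussian log densities, independently of
# the package's sufficient-statistic and finite-difference machinery
# (only the profiled optimum and Hessian locate the integration box).
quadLogMarginal <- function(object, sample, Kd, efr, kappa, noise = NULL,
                            nsd = 10) {
  fit <- laplaceLogMarginal(object, sample, Kd, efr, kappa, noise)
  sds <- sqrt(diag(solve(fit@hessian)))
  ctr <- c(fit@D0star, fit@A0star)
  e0 <- fit@Emin
  i <- if (is.character(sample)) match(sample, colnames(object)) else sample
  reps <- vapply(c("donor", "acceptor", "fret"),
                 function(ch) assay(object, ch)[, i],
                 numeric(nrow(object)))
  sig <- estimateNoise(object, sigma = noise)[i, ]
  eFun <- function(d0, a0) {
    mu <- predictIntensities(max(d0, 0), max(a0, 0), Kd, efr, kappa)
    -sum(vapply(1:3, function(k)
      sum(dnorm(reps[, k], mu[k], sig[k], log = TRUE)), numeric(1)))
  }
  inner <- function(a0) {
    g <- Vectorize(function(d0) exp(-(eFun(d0, a0) - e0)))
    integrate(g, ctr[1] - nsd * sds[1], ctr[1] + nsd * sds[1],
              rel.tol = 1e-9)$value
  }
  outer <- integrate(Vectorize(inner), ctr[2] - nsd * sds[2],
                     ctr[2] + nsd * sds[2], rel.tol = 1e-8)$value
  log(outer) - e0
}

# the three-cell study configuration used throughout: equal donor and
# acceptor totals of 0.2, 1 and 5 uM, truth Kd = 1 uM, efficiency 0.4
refStudyData <- function(seed = 7, n = 10, r = 0.05, kappa = defaultKappa()) {
  simulateFretData(Kd = 1e-6, efr = 0.4,
                   D0 = c(0.2, 1, 5) * 1e-6, A0 = c(0.2, 1, 5) * 1e-6,
                   n = n, r = r, kappa = kappa, seed = seed)
}

refStudyTruth <- list(Kd = 1e-6, efr = 0.4)
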