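# Instrument-independent apparent quantities: the apparent donor FRET
# efficiency E_d (intrinsic efficiency times the fraction of donors in
# complex) and the donor:acceptor ratio r_da = [D0]/[A0]. Under the
# reparameterization [D0] = r_da [A0], E_fr [DA] = E_d r_da [A0], the
# predicted intensities are linear in [A0], so the per-sample total is
# profiled in closed form instead of by simplex search.

# design vector: I_k = g_k * A0 with
# g_k = kappaD_k r_da + kappaA_k + (kappaF_k - kappaD_k) E_d r_da
.apparentDesign <- function(kappa, ed, rda) {
  k <- kappa@kappa
  k[, "D"] * rda + k[, "A"] + (k[, "F"] - k[, "D"]) * ed * rda
}

#' Closed-form optimal total acceptor for apparent-mode parameters
#'
#' For candidate (E_d, r_da) the predicted intensities are linear in the
#' sample's total acceptor concentration, so the posterior is maximized
#' analytically: the weighted least-squares optimum (weights 1/sigma^2)
#' of the per-channel means on the design vector, clamped at zero.
#'
#' @param object a [FretSet-class].
#' @param sample sample index or name.
#' @param ed apparent donor FRET efficiency in [0, 1].
#' @param rda donor:acceptor concentration ratio, > 0.
#' @param kappa a [KappaTable-class] (relative calibration: donor-channel
#'   donor constant = 1).
#' @param noise optional noise scales as in [estimateNoise()].
#' @return Optimal [A0] (in the concentration units implied by the kappa
#'   scale), >= 0.
#' @export
optimalA0 <- function(object, sample, ed, rda, kappa, noise = NULL) {
  if (!is.finite(ed) || ed < 0 || ed > 1) stop("ed must lie in [0, 1]")
  if (!is.finite(rda) || rda <= 0) stop("rda must be > 0")
  st <- .sampleStats(object, noise)
  i <- if (is.character(sample)) match(sample, colnames(object)) else sample
  g <- .apparentDesign(kappa, ed, rda)
  if (all(g == 0)) stop("degenerate all-zero design vector")
  m <- st[i, 2:4]
  sig <- st[i, 8:10]
  max(sum(g * m / sig^2) / sum(g^2 / sig^2), 0)
}

# residual energy of one sample at the profiled A0
.apparentEnergy <- function(stat, g) {
  if (all(g == 0)) return(Inf)
  n <- stat[1]; m <- stat[2:4]; ssq0 <- stat[5:7]; sig <- stat[8:10]
  w <- 1 / (2 * sig^2)
  a0 <- max(sum(g * m / sig^2) / sum(g^2 / sig^2), 0)
  sum(w * (ssq0 + n * (m - g * a0)^2))
}

#' Infer the apparent FRET efficiency and donor:acceptor ratio
#'
#' Metropolis-Hastings over (E_d, log10 r_da) with each sample's total
#' acceptor concentration profiled in closed form by [optimalA0()].
#' Priors: uniform on [0, 1] for E_d and uniform on log10 r_da over
#' \code{rdaBounds} (ratios span decades, and the log scale treats donor-
#' and acceptor-excess regimes symmetrically). The apparent acceptor
#' efficiency is derived per draw as \code{E_a = E_d * r_da}.
#'
#' @param object a [FretSet-class].
#' @param kappa a [KappaTable-class], calibrated relative to the
#'   donor-channel donor constant.
#' @param nChains number of chains.
#' @param nSteps recorded steps per chain.
#' @param seed master integer seed.
#' @param noise optional noise scales.
#' @param rdaBounds support of the uniform prior on log10 r_da.
#' @return list with \code{draws} (pooled post-burn-in matrix with
#'   columns \code{ed}, \code{log10_rda}, \code{ea}), \code{summary}
#'   (data.frame rows E_d, r_da, E_a), \code{psrf} and \code{proposal}.
#' @export
inferApparent <- function(object, kappa, nChains = 3L, nSteps = 10000L,
                          seed = 1L, noise = NULL, rdaBounds = c(-3, 3)) {
  stopifnot(is(object, "FretSet"), is(kappa, "KappaTable"))
  st <- .sampleStats(object, noise)
  m <- nrow(st)
  logpost <- function(x) {
    if (x[1] < 0 || x[1] > 1) return(-Inf)
    if (x[2] < rdaBounds[1] || x[2] > rdaBounds[2]) return(-Inf)
    g <- .apparentDesign(kappa, x[1], 10^x[2])
    e <- 0
    for (i in seq_len(m)) e <- e + .apparentEnergy(st[i, ], g)
    -e
  }
  set.seed(as.integer(seed))
  init <- c(runif(1, 0.1, 0.9), runif(1, -0.5, 0.5))
  fit <- .mhFitShaped(logpost, init, nChains = nChains, nSteps = nSteps,
                      seed = as.integer(seed), stepSd0 = c(0.05, 0.05),
                      stepCap = c(0.5, diff(rdaBounds) / 2))
  draws <- fit$draws
  colnames(draws) <- c("ed", "log10_rda")
  psrf <- c(ed = fit$psrf[1], log10_rda = fit$psrf[2])
  ed <- draws[, "ed"]
  rda <- 10^draws[, "log10_rda"]
  ea <- ed * rda
  summ <- function(x) {
    q <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    c(mean = mean(x), sd = .sdPop(x), cv = .sdPop(x) / mean(x),
      q05 = q[1], q50 = q[2], q95 = q[3])
  }
  list(draws = cbind(draws, ea = ea),
       summary = as.data.frame(rbind(E_d = summ(ed), r_da = summ(rda),
                                     E_a = summ(ea))),
       psrf = psrf,
       proposal = fit$stepSd)
}
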