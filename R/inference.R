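# Posterior evaluation: Gaussian likelihood, per-sample noise estimates,
# Laplace marginalization of the unknown totals (D0, A0), priors, and the
# total log-posterior over a dataset.

# finite-difference step factor for the (D0, A0) Hessian
.HFAC <- 1e-5

# Per-sample sufficient statistics: n, channel means, (n-1)*var, sigma.
# The Gaussian energy depends on the replicates only through these.
.sampleStats <- function(object, noise = NULL) {
  stopifnot(is(object, "FretSet"))
  nrep <- SummarizedExperiment::colData(object)$n_replicates
  m <- ncol(object)
  ass <- lapply(c("donor", "acceptor", "fret"),
                function(a) SummarizedExperiment::assay(object, a))
  mk <- vapply(ass, function(x) colMeans(x, na.rm = TRUE), numeric(m))
  ssq0 <- vapply(ass, function(x) {
    v <- apply(x, 2, var, na.rm = TRUE)
    ifelse(is.na(v), 0, v) * pmax(nrep - 1, 0)
  }, numeric(m))
  mk <- matrix(mk, nrow = m); ssq0 <- matrix(ssq0, nrow = m)
  sig <- estimateNoise(object, sigma = noise)
  cbind(n = nrep, mk, ssq0, sig)
}

# moment-based starting guesses for the totals, one row per sample
.momentStarts <- function(stats, kappa) {
  k <- kappa@kappa
  m1 <- stats[, 2]; m2 <- stats[, 3]
  d0 <- if (k[1, "D"] > 0) m1 / k[1, "D"] else
    rowSums(stats[, 2:4, drop = FALSE]) / sum(k[, "D"] + 1e-300)
  a0 <- if (k[2, "A"] > 0) m2 / k[2, "A"] else
    rowSums(stats[, 2:4, drop = FALSE]) / sum(k[, "A"] + 1e-300)
  cbind(pmax(d0, 0), pmax(a0, 0))
}

# per-sample Gaussian normalization constants n * sum_k log(sigma_k sqrt(2pi))
.normConst <- function(stats) {
  sig <- stats[, 8:10, drop = FALSE]
  stats[, 1] * rowSums(log(sig * sqrt(2 * pi)))
}

#' Estimate per-sample, per-channel measurement-noise scales
#'
#' The noise scale sigma of each channel of each sample is the sample
#' standard deviation of that channel's replicates (denominator n - 1),
#' floored at \code{1e-12 * (|channel mean| + 1)} so that identical
#' replicates never produce a zero scale. Noise is estimated per sample
#' because it scales with the signal, and samples can differ many-fold in
#' concentration.
#'
#' @param object a [FretSet-class].
#' @param sigma optional user-supplied scales: a length-3 vector (recycled
#'   across samples) or an m x 3 matrix. Required when samples have fewer
#'   than 2 replicates.
#' @return m x 3 numeric matrix of noise scales (columns donor, acceptor,
#'   fret).
#' @export
estimateNoise <- function(object, sigma = NULL) {
  stopifnot(is(object, "FretSet"))
  m <- ncol(object)
  if (!is.null(sigma)) {
    if (is.matrix(sigma)) {
      stopifnot(nrow(sigma) == m, ncol(sigma) == 3)
      s <- sigma
    } else {
      stopifnot(length(sigma) == 3)
      s <- matrix(sigma, m, 3, byrow = TRUE)
    }
    if (any(s <= 0)) stop("all noise scales must be > 0")
    colnames(s) <- c("donor", "acceptor", "fret")
    return(s)
  }
  nrep <- SummarizedExperiment::colData(object)$n_replicates
  if (any(nrep < 2))
    stop("samples with n < 2 replicates need an explicit 'sigma'")
  s <- vapply(c("donor", "acceptor", "fret"), function(a) {
    x <- SummarizedExperiment::assay(object, a)
    sds <- apply(x, 2, sd, na.rm = TRUE)
    mns <- colMeans(x, na.rm = TRUE)
    pmax(sds, 1e-12 * (abs(mns) + 1))
  }, numeric(m))
  s <- matrix(s, nrow = m, dimnames = list(colnames(object),
                                           c("donor", "acceptor", "fret")))
  s
}

#' Gaussian energy of one sample at given totals and parameters
#'
#' The energy is the negative log-likelihood of the sample's replicate
#' intensities under the Gaussian noise model: the sum over replicates and
#' channels of \code{(I_obs - I_pred)^2 / (2 sigma^2) + log(sigma
#' sqrt(2*pi))}, with predictions from [predictIntensities()]. The
#' normalization terms are included, so the Laplace marginal built from
#' this energy is an absolute log-likelihood.
#'
#' @param object a [FretSet-class].
#' @param sample sample index or name.
#' @param D0,A0 candidate totals, molar (negative values are clamped to 0).
#' @param Kd,efr model parameters.
#' @param kappa a [KappaTable-class].
#' @param noise optional noise scales as in [estimateNoise()].
#' @return The energy (dimensionless scalar).
#' @export
sampleEnergy <- function(object, sample, D0, A0, Kd, efr, kappa,
                         noise = NULL) {
  if (!is.finite(efr) || efr < 0 || efr > 1) stop("efr must lie in [0, 1]")
  if (Kd <= 0) stop("Kd must be > 0")
  st <- .sampleStats(object, noise)
  i <- if (is.character(sample)) match(sample, colnames(object)) else sample
  row <- unname(st[i, ])
  unname(fb_res_energy(D0, A0, Kd, efr, kappa@kappa, row) +
           .normConst(st)[i])
}

#' Profile the fluorophore totals of one sample
#'
#' Minimizes the sample energy over the unknown totals (D0, A0) >= 0 with
#' multi-start Nelder-Mead (moment-based guess, optional warm start, and
#' ten times the moment guess), returning the best optimum.
#'
#' @inheritParams sampleEnergy
#' @param start optional warm start \code{c(D0, A0)}.
#' @param multistart run all starts (default) or only the warm start.
#' @return list with \code{D0star}, \code{A0star} (molar) and
#'   \code{energy} at the optimum.
#' @export
profileTotals <- function(object, sample, Kd, efr, kappa, noise = NULL,
                          start = NULL, multistart = TRUE) {
  fit <- laplaceLogMarginal(object, sample, Kd, efr, kappa, noise, start,
                            multistart)
  list(D0star = fit@D0star, A0star = fit@A0star, energy = fit@Emin)
}

#' Laplace marginal likelihood of one sample
#'
#' Profiles the totals with [profileTotals()], evaluates the 2 x 2 Hessian
#' of the energy at the optimum by central finite differences (step
#' \code{max(1e-5 x*, 1e-12)} per coordinate), and integrates the
#' Gaussian approximation of the likelihood over (D0, A0) on
#' \code{(-Inf, Inf)^2}:
#' \code{log marginal = -E_min + log(2*pi) - 0.5 * log(det(H))}.
#' A non-positive-definite Hessian marks the fit invalid
#' (\code{logMarginal = -Inf}); it is never regularized.
#'
#' @inheritParams profileTotals
#' @return A [LaplaceFit-class].
#' @export
laplaceLogMarginal <- function(object, sample, Kd, efr, kappa, noise = NULL,
                               start = NULL, multistart = TRUE) {
  if (!is.finite(efr) || efr < 0 || efr > 1) stop("efr must lie in [0, 1]")
  if (Kd <= 0) stop("Kd must be > 0")
  st <- .sampleStats(object, noise)
  i <- if (is.character(sample)) match(sample, colnames(object)) else sample
  row <- st[i, , drop = FALSE]
  warm <- matrix(if (is.null(start)) NA_real_ else start, 1, 2, byrow = TRUE)
  res <- fb_laplace_dataset(row, Kd, efr, kappa@kappa, warm,
                            .momentStarts(row, kappa), multistart, .HFAC)
  nc <- unname(.normConst(row)[1])
  H <- matrix(res$hessian[1:4], 2, 2)
  valid <- res$valid[1]
  if (!valid)
    warning("non-positive-definite Hessian at the profiled totals; ",
            "marginal set to -Inf")
  new("LaplaceFit",
      D0star = res$optima[1, 1], A0star = res$optima[1, 2],
      Emin = res$emin[1] + nc, hessian = H,
      logMarginal = if (valid)
        -(res$emin[1] + nc) + log(2 * pi) - 0.5 * res$logdet[1] else -Inf,
      valid = valid)
}

#' Log prior density of (Kd, E_fr)
#'
#' Sum of the log prior densities: uniform on log10(Kd) over the prior
#' bounds, and either uniform on [0, 1] or a truncated Gaussian for the
#' efficiency. Returns \code{-Inf} outside the support.
#'
#' @param log10Kd log10 of the dissociation constant (log10 molar).
#' @param efr FRET efficiency.
#' @param prior a [FretPrior-class].
#' @return Log density (the density is normalized over the support).
#' @export
logPrior <- function(log10Kd, efr, prior = fretPrior()) {
  stopifnot(is(prior, "FretPrior"))
  b <- prior@kdBounds
  if (!is.finite(log10Kd) || log10Kd < b[1] || log10Kd > b[2]) return(-Inf)
  if (!is.finite(efr) || efr < 0 || efr > 1) return(-Inf)
  lp <- -log(b[2] - b[1])
  if (!is.na(prior@efrMean)) {
    mu <- prior@efrMean; s <- prior@efrSd
    lp <- lp + dnorm(efr, mu, s, log = TRUE) -
      log(pnorm((1 - mu) / s) - pnorm((0 - mu) / s))
  }
  lp
}

# Closure over precomputed statistics with a warm-start store. commit()
# promotes the optima of the last evaluated proposal to warm starts (call
# it when the MCMC accepts).
.posteriorFactory <- function(object, kappa, prior, noise = NULL,
                              multistart = TRUE) {
  st <- .sampleStats(object, noise)
  moment <- .momentStarts(st, kappa)
  normTotal <- sum(.normConst(st))
  kap <- kappa@kappa
  warm <- moment
  pending <- NULL
  logpost <- function(par) {
    lp <- logPrior(par[1], par[2], prior)
    if (!is.finite(lp)) return(-Inf)
    res <- fb_laplace_dataset(st, 10^par[1], par[2], kap, warm, moment,
                              multistart, .HFAC)
    if (!res$all_valid) return(-Inf)
    pending <<- res$optima
    lp + res$total - normTotal
  }
  commit <- function() if (!is.null(pending)) warm <<- pending
  list(logpost = logpost, commit = commit)
}

#' Total log posterior of (Kd, E_fr) for a dataset
#'
#' Log prior plus the sum over samples of the Laplace-marginalized
#' log-likelihood (samples are independent). Any sample with an invalid
#' Laplace fit makes the result \code{-Inf}.
#'
#' @param object a [FretSet-class].
#' @param Kd dissociation constant, molar.
#' @param efr FRET efficiency.
#' @param kappa a [KappaTable-class].
#' @param prior a [FretPrior-class].
#' @param noise optional noise scales as in [estimateNoise()].
#' @return Log posterior (unnormalized by the evidence).
#' @export
logPosterior <- function(object, Kd, efr, kappa, prior = fretPrior(),
                         noise = NULL) {
  if (Kd <= 0) stop("Kd must be > 0")
  fac <- .posteriorFactory(object, kappa, prior, noise)
  fac$logpost(c(log10(Kd), efr))
}

#' Energy over a (log10 Kd, E_fr) grid
#'
#' Evaluates the energy, the negative log posterior, at every node of a
#' rectangular grid; useful for contour plots of the posterior surface.
#'
#' @param object a [FretSet-class].
#' @param kdGrid numeric vector of log10(Kd) values (log10 molar).
#' @param efrGrid numeric vector of efficiencies in [0, 1].
#' @param kappa a [KappaTable-class].
#' @param prior a [FretPrior-class].
#' @param noise optional noise scales.
#' @return matrix of energies, rows indexed by \code{kdGrid}, columns by
#'   \code{efrGrid}.
#' @export
energyGrid <- function(object, kdGrid, efrGrid, kappa,
                       prior = fretPrior(), noise = NULL) {
  stopifnot(length(kdGrid) >= 1, length(efrGrid) >= 1)
  fac <- .posteriorFactory(object, kappa, prior, noise)
  out <- matrix(NA_real_, length(kdGrid), length(efrGrid),
                dimnames = list(format(kdGrid, trim = TRUE),
                                format(efrGrid, trim = TRUE)))
  for (j in seq_along(efrGrid)) for (i in seq_along(kdGrid)) {
    out[i, j] <- -fac$logpost(c(kdGrid[i], efrGrid[j]))
    fac$commit()
  }
  out
}
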