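#' Default kappa constants for simulation
#'
#' A donor-acceptor pair with considerable spectral cross-talk and
#' bleed-through: each species is brightest in its own channel, the donor
#' and acceptor are not equally bright, the donor bleed-through and
#' acceptor cross-talk into the FRET channel are about 20% of the
#' respective own-channel constants, and the acceptor contributions in the
#' donor channel are very small but nonzero (any measurable contamination
#' can be represented).
#'
#' @return A [KappaTable-class] with \code{kappa_D = (1, 0.05, 0.2)},
#'   \code{kappa_A = (0.01, 0.75, 0.15)}, \code{kappa_F = (0.01, 0.05,
#'   0.75)} intensity per molar (channel order donor, acceptor, FRET).
#' @export
defaultKappa <- function() {
  KappaTable(kappa_D = c(1.0, 0.05, 0.2),
             kappa_A = c(0.01, 0.75, 0.15),
             kappa_F = c(0.01, 0.05, 0.75))
}

#' Simulate a three-cube FRET dataset
#'
#' For each sample the noiseless channel intensities are computed with
#' [predictIntensities()]; each of the \code{n} replicate measurements per
#' channel then receives independent Gaussian noise with standard
#' deviation \code{r} times that channel's noiseless mean for that sample
#' (noise scales with the local signal). Negative noisy intensities are
#' kept: the Gaussian likelihood is defined on all reals and clamping
#' would bias the inference.
#'
#' @param Kd dissociation constant, molar, > 0.
#' @param efr intrinsic FRET efficiency in [0, 1].
#' @param D0,A0 numeric vectors (length m) of total donor and acceptor
#'   concentrations, one entry per sample.
#' @param n replicate measurements per sample per channel (>= 1).
#' @param r relative noise strength in [0, 1): noise SD as a fraction of
#'   the per-sample, per-channel noiseless mean.
#' @param kappa a [KappaTable-class]; defaults to [defaultKappa()].
#' @param seed integer RNG seed; fixed seed gives a bit-identical dataset.
#' @param units \code{"M"} (default) or \code{"uM"} for the concentration
#'   arguments; internally everything is molar.
#' @return A [FretSet-class] with the generating configuration in
#'   \code{metadata()$simulation} and per-sample truths in \code{colData()}.
#' @examples
#' fs <- simulateFretData(Kd = 1e-6, efr = 0.4, D0 = c(0.2, 1, 5) * 1e-6,
#'                        A0 = c(0.2, 1, 5) * 1e-6, n = 10, r = 0.05,
#'                        seed = 1)
#' fs
#' @export
simulateFretData <- function(Kd, efr, D0, A0, n, r, kappa = defaultKappa(),
                             seed = 1L, units = c("M", "uM")) {
  units <- match.arg(units)
  if (units == "uM") { D0 <- D0 * 1e-6; A0 <- A0 * 1e-6 }
  m <- length(D0)
  if (length(A0) != m || m < 1)
    stop("D0 and A0 must be equal-length, nonempty vectors")
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(r) || r < 0 || r >= 1) stop("r must lie in [0, 1)")
  stopifnot(is(kappa, "KappaTable"))
  set.seed(as.integer(seed))
  ch <- lapply(1:3, function(k) matrix(NA_real_, n, m))
  for (j in seq_len(m)) {
    mu <- predictIntensities(D0[j], A0[j], Kd, efr, kappa)
    for (k in 1:3) {
      ch[[k]][, j] <- if (r == 0) rep(mu[k], n) else rnorm(n, mu[k], r * mu[k])
    }
  }
  cfg <- list(Kd = Kd, efr = efr, D0 = D0, A0 = A0, n = n, r = r,
              kappa = kappa@kappa, seed = as.integer(seed))
  FretSet(donor = ch[[1]], acceptor = ch[[2]], fret = ch[[3]],
          sampleData = data.frame(D0 = D0, A0 = A0),
          metadata = list(simulation = cfg))
}

#' Simulate a calibration dataset
#'
#' Generates the three calibration blocks: a donor-only sample at
#' concentration \code{cD}, an acceptor-only sample at \code{cA}, and a
#' tandem donor-acceptor construct sample at \code{cDA} with construct
#' FRET efficiency \code{efrConstruct} (every construct molecule is a 1:1
#' complex). Noise is Gaussian with SD \code{r} times the channel mean, as
#' in [simulateFretData()].
#'
#' @param kappa a [KappaTable-class]: generating constants.
#' @param efrConstruct construct FRET efficiency in [0, 1].
#' @param cD,cA,cDA block concentrations, molar.
#' @param n replicates per channel per block.
#' @param r relative noise strength in [0, 1).
#' @param seed integer RNG seed.
#' @return A [FretSet-class] with samples \code{donor_only},
#'   \code{acceptor_only}, \code{construct}.
#' @export
simulateCalibrationData <- function(kappa, efrConstruct, cD = 1e-6,
                                    cA = 1e-6, cDA = 1e-6, n = 20,
                                    r = 0.03, seed = 1L) {
  stopifnot(is(kappa, "KappaTable"))
  if (efrConstruct < 0 || efrConstruct > 1)
    stop("efrConstruct must lie in [0, 1]")
  set.seed(as.integer(seed))
  k <- kappa@kappa
  mus <- cbind(donor_only = k[, "D"] * cD,
               acceptor_only = k[, "A"] * cA,
               construct = (k[, "D"] * (1 - efrConstruct) + k[, "A"] +
                              k[, "F"] * efrConstruct) * cDA)
  ch <- lapply(1:3, function(k) matrix(NA_real_, n, 3,
                                       dimnames = list(NULL, colnames(mus))))
  for (j in 1:3) for (kk in 1:3) {
    mu <- mus[kk, j]
    ch[[kk]][, j] <- if (r == 0) rep(mu, n) else rnorm(n, mu, r * mu)
  }
  FretSet(donor = ch[[1]], acceptor = ch[[2]], fret = ch[[3]],
          metadata = list(calibration = list(
            kappa = k, efrConstruct = efrConstruct,
            concentrations = c(donor_only = cD, acceptor_only = cA,
                               construct = cDA),
            n = n, r = r, seed = as.integer(seed))))
}
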