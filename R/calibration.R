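# Calibration of the kappa constants from donor-only, acceptor-only and
# tandem-construct three-cube measurements. Absolute mode divides by known
# concentrations; relative mode fixes the donor-channel donor constant to
# unity and samples the remaining constants and the construct efficiency
# from a posterior in which each block's unknown concentration is
# Laplace-marginalized and the shared noise scale is integrated out under
# a Jeffreys prior.

# sufficient stats of one calibration block: n, means, (n-1)*var, sigma
.blockStats <- function(object, block, noise = NULL) {
  if (!block %in% colnames(object))
    stop(sprintf("calibration block '%s' not present in the dataset", block))
  st <- .sampleStats(object, noise)
  st[match(block, colnames(object)), ]
}

# log marginal likelihood of one block with design vector g (predicted
# intensity = g * c for unknown concentration c >= 0).
# shared mode: Jeffreys 1/sigma shared across the three channels,
#   integrated analytically -> Student-type S(c)^(-3n/2); then 1-D Laplace
#   over c at the least-squares optimum.
# perChannel mode: per-channel sigma plugged in; weighted least squares
#   optimum, Gaussian energy, 1-D Laplace over c.
.calibBlockML <- function(stat, g, sigmaMode = c("shared", "perChannel")) {
  sigmaMode <- match.arg(sigmaMode)
  n <- stat[1]
  m <- stat[2:4]
  ssq0 <- stat[5:7]
  sig <- stat[8:10]
  if (all(g == 0)) return(-Inf)
  if (sigmaMode == "shared") {
    N <- 3 * n
    S <- function(c) sum(ssq0 + n * (m - g * c)^2)
    cs <- max(sum(g * m) / sum(g * g), 0)
    if (S(cs) < .Machine$double.xmin) return(Inf)  # exact fit: degenerate
    E <- function(c) (N / 2) * log(S(max(c, 0)))
    h <- max(.HFAC * cs, 1e-12)
    E2 <- (E(cs + h) - 2 * E(cs) + E(cs - h)) / h^2
    if (!is.finite(E2) || E2 <= 0) return(-Inf)
    # log of (1/2) Gamma(N/2) pi^(-N/2) S(c*)^(-N/2) * sqrt(2 pi / E'')
    lgamma(N / 2) - log(2) - (N / 2) * log(pi) - (N / 2) * log(S(cs)) +
      0.5 * log(2 * pi) - 0.5 * log(E2)
  } else {
    w <- 1 / (2 * sig^2)
    cs <- max(sum(g * m / sig^2) / sum(g^2 / sig^2), 0)
    E <- function(c) sum(w * (ssq0 + n * (m - g * max(c, 0))^2)) +
      n * sum(log(sig * sqrt(2 * pi)))
    h <- max(.HFAC * cs, 1e-12)
    E2 <- (E(cs + h) - 2 * E(cs) + E(cs - h)) / h^2
    if (!is.finite(E2) || E2 <= 0) return(-Inf)
    -E(cs) + 0.5 * log(2 * pi) - 0.5 * log(E2)
  }
}

# construct-block design vector for candidate constants and efficiency
.constructDesign <- function(k, efr)
  k[, "D"] * (1 - efr) + k[, "A"] + k[, "F"] * efr

#' Absolute calibration from samples of known concentration
#'
#' When the fluorophore concentrations of the calibration samples are
#' known, the donor and acceptor constants follow directly from the
#' channel means: \code{kappa_i^D = mean(I_i, donor-only) / [D0]} and
#' \code{kappa_i^A = mean(I_i, acceptor-only) / [A0]}. Uncertainties are
#' standard errors of the channel means divided by the concentration.
#' The FRET-sensitized constants are not identified by these two samples;
#' fill them with [fretKappaFromExtinction()].
#'
#' @param object a [FretSet-class] containing samples named
#'   \code{donor_only} and \code{acceptor_only}.
#' @param concentrations named numeric: \code{donor_only} and
#'   \code{acceptor_only} concentrations, molar, > 0.
#' @return A [CalibrationResult-class] (absolute mode; \code{kappa_F}
#'   left at zero).
#' @export
calibrateAbsolute <- function(object, concentrations) {
  stopifnot(is(object, "FretSet"))
  cD <- concentrations[["donor_only"]]
  cA <- concentrations[["acceptor_only"]]
  if (!is.finite(cD) || cD <= 0 || !is.finite(cA) || cA <= 0)
    stop("calibration concentrations must be positive")
  std <- .blockStats(object, "donor_only")
  sta <- .blockStats(object, "acceptor_only")
  kD <- std[2:4] / cD
  kA <- sta[2:4] / cA
  seD <- sqrt(std[5:7] / pmax(std[1] - 1, 1)) / sqrt(std[1]) / cD
  seA <- sqrt(sta[5:7] / pmax(sta[1] - 1, 1)) / sqrt(sta[1]) / cA
  new("CalibrationResult",
      kappa = KappaTable(pmax(kD, 0), pmax(kA, 0), c(0, 0, 0)),
      efrConstruct = NA_real_,
      se = data.frame(channel = c("donor", "acceptor", "fret"),
                      kappa_D = seD, kappa_A = seA, row.names = NULL),
      mode = "absolute",
      scaleNote = paste("absolute mode: kappa in intensity per molar;",
                        "kappa_F not identified here - derive it with",
                        "fretKappaFromExtinction()"),
      draws = matrix(numeric(0), 0, 0))
}

#' FRET-sensitized constants from extinction-coefficient ratios
#'
#' FRET-sensitized emission is acceptor emission driven by donor
#' absorption: the constant factorizes into the same acceptor quantum
#' yield and detection terms as \code{kappa_i^A} but with the donor's
#' molar extinction coefficient at channel i's excitation wavelength.
#' Hence \code{kappa_i^F = kappa_i^A * (eps_i^D / eps_i^A)}.
#'
#' @param kappa a [KappaTable-class] (its \code{kappa_F} column is
#'   replaced) or a numeric(3) of acceptor constants.
#' @param ratio numeric(3) of per-channel extinction-coefficient ratios
#'   \code{eps_i^D / eps_i^A}, all > 0 and finite.
#' @return Same type as \code{kappa}: a new [KappaTable-class] or the
#'   numeric(3) of FRET constants.
#' @export
fretKappaFromExtinction <- function(kappa, ratio) {
  if (length(ratio) != 3 || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be three positive finite values")
  if (is(kappa, "KappaTable"))
    return(KappaTable(kappaD(kappa), kappaA(kappa), kappaA(kappa) * ratio))
  stopifnot(is.numeric(kappa), length(kappa) == 3)
  kappa * ratio
}

#' Calibration log posterior for candidate constants
#'
#' Sum over the available calibration blocks (donor-only, acceptor-only,
#' construct) of the per-block log marginal likelihood, with each block's
#' single unknown concentration integrated out by a 1-D Laplace
#' approximation and the noise scale handled per \code{sigmaMode}:
#' \code{"shared"} (default) integrates one shared sigma per block under a
#' Jeffreys prior; \code{"perChannel"} plugs in the per-channel replicate
#' SDs. The candidate table must satisfy the relative gauge
#' \code{kappa_D[donor channel] = 1} (the likelihood is invariant under
#' jointly rescaling all constants and inverting the concentrations, so
#' one constant must be pinned).
#'
#' @param object a [FretSet-class] with samples among \code{donor_only},
#'   \code{acceptor_only}, \code{construct}.
#' @param kappa candidate [KappaTable-class] (gauge-fixed).
#' @param efrConstruct candidate construct FRET efficiency in [0, 1]
#'   (used by the construct block).
#' @param sigmaMode \code{"shared"} or \code{"perChannel"}.
#' @param noise optional noise scales (perChannel mode).
#' @param gauge check the \code{kappa_D[1] == 1} gauge (default TRUE).
#' @return Log posterior (\code{-Inf} outside the support).
#' @export
calibLogPosterior <- function(object, kappa, efrConstruct,
                              sigmaMode = c("shared", "perChannel"),
                              noise = NULL, gauge = TRUE) {
  stopifnot(is(object, "FretSet"), is(kappa, "KappaTable"))
  sigmaMode <- match.arg(sigmaMode)
  k <- kappa@kappa
  if (any(k < 0)) return(-Inf)
  if (!is.finite(efrConstruct) || efrConstruct < 0 || efrConstruct > 1)
    return(-Inf)
  if (gauge && abs(k[1, "D"] - 1) > 1e-9)
    stop("relative calibration requires the gauge kappa_D[1] = 1")
  blocks <- intersect(c("donor_only", "acceptor_only", "construct"),
                      colnames(object))
  if (length(blocks) == 0) stop("no calibration blocks in dataset")
  total <- 0
  for (b in blocks) {
    stat <- .blockStats(object, b, noise)
    g <- switch(b,
                donor_only = k[, "D"],
                acceptor_only = k[, "A"],
                construct = .constructDesign(k, efrConstruct))
    total <- total + .calibBlockML(stat, g, sigmaMode)
  }
  total
}

#' Relative calibration by MCMC
#'
#' Samples the five free kappa ratios (all constants relative to the
#' donor-channel donor constant, fixed at 1) and the construct FRET
#' efficiency from the calibration posterior with the same
#' Metropolis-Hastings machinery as the main fit: the five ratios move on
#' the log10 scale, the efficiency on its natural scale; two chains are
#' run, step sizes are tuned to the 40-60% acceptance band, burn-in is
#' discarded and convergence is checked. The FRET-sensitized constants
#' are tied to the acceptor constants through the extinction ratios.
#'
#' @param object a [FretSet-class] with all three blocks
#'   \code{donor_only}, \code{acceptor_only} and \code{construct}.
#' @param ratio numeric(3) extinction-coefficient ratios for
#'   [fretKappaFromExtinction()].
#' @param nSteps recorded steps per chain.
#' @param seed master integer seed.
#' @param sigmaMode see [calibLogPosterior()].
#' @param noise optional noise scales (perChannel mode).
#' @return A [CalibrationResult-class] (relative mode) with posterior
#'   means in the kappa table, posterior SDs in \code{se}, and the pooled
#'   draws.
#' @export
calibrateRelative <- function(object, ratio, nSteps = 10000L, seed = 1L,
                              sigmaMode = c("shared", "perChannel"),
                              noise = NULL) {
  stopifnot(is(object, "FretSet"))
  sigmaMode <- match.arg(sigmaMode)
  need <- c("donor_only", "acceptor_only", "construct")
  miss <- setdiff(need, colnames(object))
  if (length(miss) > 0)
    stop("relative calibration needs all three blocks; missing: ",
         paste(miss, collapse = ", "),
         if ("construct" %in% miss)
           " (without the construct, kappa_F and the construct efficiency are unidentifiable)"
         else "")
  if (length(ratio) != 3 || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be three positive finite values")

  stats <- lapply(need, .blockStats, object = object, noise = noise)
  names(stats) <- need
  parNames <- c("log10_kd2", "log10_kd3", "log10_ka1", "log10_ka2",
                "log10_ka3", "efr_construct")
  logpost <- function(x) {
    if (any(!is.finite(x)) || any(abs(x[1:5]) > 12)) return(-Inf)
    if (x[6] < 0 || x[6] > 1) return(-Inf)
    kD <- c(1, 10^x[1], 10^x[2])
    kA <- 10^x[3:5]
    .calibBlockML(stats$donor_only, kD, sigmaMode) +
      .calibBlockML(stats$acceptor_only, kA, sigmaMode) +
      .calibBlockML(stats$construct,
                    kD * (1 - x[6]) + kA + kA * ratio * x[6], sigmaMode)
  }

  # moment-based init: donor-only means fix the kappa_D ratios directly;
  # acceptor block enters only through ratios once its concentration is
  # marginalized, so any positive scale guess works for kappa_A
  md <- stats$donor_only[2:4]
  ma <- stats$acceptor_only[2:4]
  ref <- max(md[1], 1e-300)
  init <- c(log10(pmax(md[2:3] / ref, 1e-6)),
            log10(pmax(ma / ref, 1e-6)), 0.5)

  # the acceptor scale and the construct efficiency are strongly
  # correlated (only the construct block pins them jointly), so the
  # sampler pipeline learns the posterior covariance in a pilot phase and
  # records with covariance-shaped proposals
  fit <- .mhFitShaped(logpost, init, nChains = 2L, nSteps = nSteps,
                      seed = as.integer(seed),
                      stepSd0 = c(rep(0.05, 5), 0.05), stepCap = rep(2, 6))
  draws <- fit$draws
  colnames(draws) <- parNames
  psrf <- fit$psrf
  if (any(psrf >= 1.2))
    stop("calibration chains did not converge (PSRF: ",
         paste(sprintf("%.2f", psrf), collapse = ", "), ")")

  nat <- cbind(kd2 = 10^draws[, 1], kd3 = 10^draws[, 2],
               ka1 = 10^draws[, 3], ka2 = 10^draws[, 4],
               ka3 = 10^draws[, 5], efr_construct = draws[, 6])
  mn <- colMeans(nat)
  sds <- apply(nat, 2, .sdPop)
  kD <- c(1, mn[["kd2"]], mn[["kd3"]])
  kA <- c(mn[["ka1"]], mn[["ka2"]], mn[["ka3"]])
  new("CalibrationResult",
      kappa = KappaTable(kD, kA, kA * ratio),
      efrConstruct = mn[["efr_construct"]],
      se = data.frame(parameter = colnames(nat), mean = mn, sd = sds,
                      row.names = NULL),
      mode = "relative",
      scaleNote = paste("relative mode: constants are ratios to the",
                        "donor-channel donor constant (set to 1);",
                        "downstream Kd estimates are scaled by that",
                        "reference constant"),
      draws = nat)
}
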