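#' @import methods
#' @importFrom stats sd var cor rnorm runif dnorm pnorm qnorm quantile
#'   optim integrate setNames
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib fretBayes, .registration = TRUE
NULL

#' Photophysical constants mapping species concentrations to intensities
#'
#' A \code{KappaTable} holds the nine kappa constants of the three-cube
#' spectral mixing model: for each spectral channel (donor, acceptor, FRET)
#' the proportionality factor between the concentration of free donor,
#' free acceptor, or FRET-sensitized emission from the complex and the
#' fluorescence intensity observed in that channel. Each constant folds
#' together illumination intensity, molar extinction, quantum yield and
#' detector sensitivity; the individual photophysical factors are never
#' needed separately.
#'
#' @slot kappa 3 x 3 numeric matrix; rows are channels
#'   (\code{donor}, \code{acceptor}, \code{fret}), columns are species
#'   contributions (\code{D}, \code{A}, \code{F}). Units: intensity per
#'   molar. All entries must be nonnegative and at least one positive.
#'
#' @seealso [KappaTable()], [defaultKappa()], [mixingMatrix()]
#' @export
setClass("KappaTable", representation(kappa = "matrix"))

setValidity("KappaTable", function(object) {
  k <- object@kappa
  if (!is.numeric(k) || !identical(dim(k), c(3L, 3L)))
    return("kappa must be a 3 x 3 numeric matrix")
  if (anyNA(k)) return("kappa must not contain NA")
  if (any(k < 0)) return("all kappa constants must be >= 0")
  if (all(k == 0)) return("at least one kappa constant must be > 0")
  TRUE
})

#' Construct a KappaTable
#'
#' @param kappa_D,kappa_A,kappa_F numeric(3): per-channel constants for the
#'   free donor, free acceptor, and FRET-sensitized emission contribution of
#'   the complex. Channel order: donor, acceptor, FRET.
#' @return A [KappaTable-class] object.
#' @examples
#' kt <- KappaTable(c(1, 0.05, 0.2), c(0.01, 0.75, 0.15), c(0.01, 0.05, 0.75))
#' kappaD(kt)
#' @export
KappaTable <- function(kappa_D, kappa_A, kappa_F) {
  k <- cbind(D = as.numeric(kappa_D), A = as.numeric(kappa_A),
             F = as.numeric(kappa_F))
  rownames(k) <- c("donor", "acceptor", "fret")
  new("KappaTable", kappa = k)
}

#' @describeIn KappaTable per-channel constants for the free donor
#' @param object a \code{KappaTable}
#' @export
kappaD <- function(object) object@kappa[, "D"]

#' @describeIn KappaTable per-channel constants for the free acceptor
#' @export
kappaA <- function(object) object@kappa[, "A"]

#' @describeIn KappaTable per-channel FRET-sensitized emission constants
#' @export
kappaF <- function(object) object@kappa[, "F"]

setMethod("show", "KappaTable", function(object) {
  cat("KappaTable (intensity per molar; rows = channels)\n")
  print(object@kappa)
})

#' Three-cube FRET intensity data
#'
#' \code{FretSet} extends \code{SummarizedExperiment}: columns are samples
#' (cells or regions of interest), rows are replicate measurements, and the
#' three assays \code{donor}, \code{acceptor} and \code{fret} hold the
#' background-corrected intensities from the three spectral channels.
#' Samples with fewer replicates than the widest sample are padded with
#' \code{NA}; \code{colData()$n_replicates} records the true count.
#' Simulated datasets carry their generating configuration in
#' \code{metadata()$simulation}.
#'
#' @seealso [FretSet()], [simulateFretData()], [readFretData()]
#' @import SummarizedExperiment
#' @export
setClass("FretSet", contains = "SummarizedExperiment")

setValidity("FretSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("donor", "acceptor", "fret") %in% an))
    return("assays 'donor', 'acceptor' and 'fret' are required")
  if (!"n_replicates" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain 'n_replicates'")
  nr <- SummarizedExperiment::colData(object)$n_replicates
  for (a in c("donor", "acceptor", "fret")) {
    cnt <- colSums(!is.na(SummarizedExperiment::assay(object, a)))
    if (!all(cnt == nr))
      return(sprintf(
        "channel '%s': non-NA replicate counts disagree with n_replicates", a))
  }
  TRUE
})

#' Construct a FretSet from per-channel intensity matrices
#'
#' @param donor,acceptor,fret numeric matrices (replicates x samples) of
#'   intensities from the donor, acceptor and FRET channels. Samples with
#'   fewer replicates are NA-padded; the three channels of a sample must
#'   have equal replicate counts.
#' @param sampleData optional \code{DataFrame}/\code{data.frame} of
#'   per-sample annotation (e.g. true \code{D0}, \code{A0} for simulated
#'   data).
#' @param metadata optional list stored in the object metadata.
#' @return A [FretSet-class].
#' @export
FretSet <- function(donor, acceptor, fret, sampleData = NULL,
                    metadata = list()) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  fret <- as.matrix(fret)
  if (!all(dim(donor) == dim(acceptor)) || !all(dim(donor) == dim(fret)))
    stop("channel matrices must have identical dimensions")
  nrep <- colSums(!is.na(donor))
  for (a in list(acceptor, fret)) {
    if (!all(colSums(!is.na(a)) == nrep))
      stop("replicate counts differ between channels within a sample")
  }
  m <- ncol(donor)
  if (is.null(colnames(donor)))
    colnames(donor) <- colnames(acceptor) <- colnames(fret) <-
      paste0("sample", seq_len(m))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(donor))
        else S4Vectors::DataFrame(sampleData, row.names = colnames(donor))
  cd$n_replicates <- as.integer(nrep)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(donor = donor, acceptor = acceptor, fret = fret),
    colData = cd, metadata = metadata)
  new("FretSet", se)
}

#' Prior specification for (Kd, E_fr)
#'
#' The dissociation constant carries a uniform prior on log10(Kd) over a
#' bounded support (default [-12, -2] in log10 molar). The FRET efficiency
#' prior is either uniform on [0, 1] or a Gaussian truncated to [0, 1],
#' e.g. centred at an independently measured efficiency.
#'
#' @slot efrMean,efrSd numeric; \code{NA} for the uniform efficiency prior,
#'   otherwise the mean and standard deviation of the truncated Gaussian.
#' @slot kdBounds numeric(2); support of log10(Kd) in log10 molar.
#' @seealso [fretPrior()], [logPrior()]
#' @export
setClass("FretPrior", representation(efrMean = "numeric", efrSd = "numeric",
                                     kdBounds = "numeric"))

setValidity("FretPrior", function(object) {
  b <- object@kdBounds
  if (length(b) != 2 || anyNA(b) || b[1] >= b[2])
    return("kdBounds must be increasing numeric(2)")
  if (!is.na(object@efrMean) && (is.na(object@efrSd) || object@efrSd <= 0))
    return("a Gaussian efficiency prior needs efrSd > 0")
  TRUE
})

#' Construct a prior for (Kd, E_fr)
#'
#' @param efr \code{NULL} for a uniform efficiency prior on [0, 1], or
#'   \code{c(mean, sd)} for a Gaussian truncated to [0, 1].
#' @param kdBounds support of the uniform prior on log10(Kd), in log10
#'   molar. A bounded support keeps the posterior proper when the data only
#'   bound Kd from one side (concentration plateaus).
#' @return A [FretPrior-class].
#' @examples
#' fretPrior()                      # uniform on both parameters
#' fretPrior(efr = c(0.45, 0.15))   # efficiency measured independently
#' @export
fretPrior <- function(efr = NULL, kdBounds = c(-12, -2)) {
  if (is.null(efr)) {
    new("FretPrior", efrMean = NA_real_, efrSd = NA_real_,
        kdBounds = as.numeric(kdBounds))
  } else {
    stopifnot(length(efr) == 2)
    new("FretPrior", efrMean = as.numeric(efr[1]), efrSd = as.numeric(efr[2]),
        kdBounds = as.numeric(kdBounds))
  }
}

setMethod("show", "FretPrior", function(object) {
  if (is.na(object@efrMean)) cat("E_fr prior : uniform on [0, 1]\n")
  else cat(sprintf("E_fr prior : Gaussian(%.3g, sd %.3g) truncated to [0, 1]\n",
                   object@efrMean, object@efrSd))
  cat(sprintf("Kd prior   : uniform on log10 Kd in [%g, %g] (log10 M)\n",
              object@kdBounds[1], object@kdBounds[2]))
})

#' Symmetric Gaussian random-walk proposal
#'
#' @slot stepLogKd,stepEfr standard deviations of the independent Gaussian
#'   proposal increments in log10(Kd) and in the efficiency coordinate.
#' @seealso [proposalSpec()], [tuneStepSize()]
#' @export
setClass("ProposalSpec",
         representation(stepLogKd = "numeric", stepEfr = "numeric"))

setValidity("ProposalSpec", function(object) {
  if (object@stepLogKd <= 0 || object@stepEfr <= 0)
    return("proposal step SDs must be > 0")
  TRUE
})

#' @describeIn ProposalSpec constructor
#' @param stepLogKd,stepEfr positive proposal step SDs.
#' @export
proposalSpec <- function(stepLogKd, stepEfr)
  new("ProposalSpec", stepLogKd = stepLogKd, stepEfr = stepEfr)

setMethod("show", "ProposalSpec", function(object) {
  cat(sprintf("ProposalSpec: step SD log10(Kd) = %.4g, E_fr = %.4g\n",
              object@stepLogKd, object@stepEfr))
})

#' Laplace marginalization of the fluorophore totals for one sample
#'
#' Result of minimizing the energy (negative log-likelihood) over the
#' unknown totals (D0, A0) of one sample and integrating the likelihood
#' over them with a Gaussian (Laplace) approximation around the optimum.
#'
#' @slot D0star,A0star maximizing totals, molar.
#' @slot Emin energy at the optimum (includes the Gaussian normalization
#'   terms, so \code{logMarginal} is an absolute log-likelihood).
#' @slot hessian 2 x 2 second-derivative matrix of the energy with respect
#'   to (D0, A0) at the optimum.
#' @slot logMarginal \code{-Emin + log(2*pi) - 0.5*log(det(hessian))}.
#' @slot valid \code{TRUE} when the Hessian is positive definite.
#' @seealso [laplaceLogMarginal()]
#' @export
setClass("LaplaceFit",
         representation(D0star = "numeric", A0star = "numeric",
                        Emin = "numeric", hessian = "matrix",
                        logMarginal = "numeric", valid = "logical"))

setMethod("show", "LaplaceFit", function(object) {
  cat(sprintf("LaplaceFit: D0* = %.4g M, A0* = %.4g M\n",
              object@D0star, object@A0star))
  cat(sprintf("  E_min = %.6g, log marginal = %.6g, valid = %s\n",
              object@Emin, object@logMarginal, object@valid))
})

#' Metropolis-Hastings chains over (log10 Kd, E_fr)
#'
#' @slot states list of matrices (one per chain), columns are the sampled
#'   coordinates (for the main mode \code{log10_kd}, \code{efr}).
#' @slot energies list of numeric vectors: -log posterior per recorded
#'   state.
#' @slot accepted list of logical vectors: proposal acceptance flags
#'   (first entry \code{NA}: the initial state is not a proposal).
#' @slot burnIn integer vector: per-chain burn-in index (NA before
#'   detection).
#' @slot proposal the frozen [ProposalSpec-class] used for recording.
#' @slot seeds integer vector of per-chain seeds.
#' @seealso [runChain()], [fitKd()], [summarizePosterior()]
#' @export
setClass("FretChains",
         representation(states = "list", energies = "list",
                        accepted = "list", burnIn = "integer",
                        proposal = "ProposalSpec", seeds = "integer"))

#' @describeIn FretChains number of chains
#' @param object a \code{FretChains}
#' @export
nChains <- function(object) length(object@states)

#' @describeIn FretChains list of per-chain state matrices
#' @export
chainStates <- function(object) object@states

#' @describeIn FretChains list of per-chain energy (-log posterior) vectors
#' @export
chainEnergies <- function(object) object@energies

#' @describeIn FretChains empirical acceptance fraction of each chain
#' @export
acceptanceRate <- function(object)
  vapply(object@accepted, function(a) mean(a[-1]), numeric(1))

#' @describeIn FretChains per-chain burn-in indices
#' @export
burnIn <- function(object) object@burnIn

setMethod("show", "FretChains", function(object) {
  cat(sprintf("FretChains: %d chain(s) x %d states, parameters: %s\n",
              nChains(object), nrow(object@states[[1]]),
              paste(colnames(object@states[[1]]), collapse = ", ")))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%.1f%%", 100 * acceptanceRate(object)),
                    collapse = ", ")))
  cat(sprintf("  burn-in: %s\n",
              paste(object@burnIn, collapse = ", ")))
})

#' Complete posterior fit of (Kd, E_fr)
#'
#' Returned by [fitKd()]: tuned proposal, recorded chains, convergence
#' report and posterior summary.
#'
#' @slot chains a [FretChains-class]
#' @slot summary data.frame of posterior summaries (rows Kd, E_fr)
#' @slot convergence list with PSRF values and the overlap flag
#' @slot proposal the tuned [ProposalSpec-class]
#' @export
setClass("FretFit",
         representation(chains = "FretChains", summary = "data.frame",
                        convergence = "list", proposal = "ProposalSpec"))

setMethod("show", "FretFit", function(object) {
  cat("FretFit\n")
  show(object@proposal)
  cat(sprintf("  PSRF: %s (pass = %s)\n",
              paste(sprintf("%s = %.3f", names(object@convergence$psrf),
                            object@convergence$psrf), collapse = ", "),
              object@convergence$pass))
  print(object@summary)
})

#' @describeIn FretFit posterior summary table
#' @param object a \code{FretFit}
#' @export
posteriorSummary <- function(object) object@summary

#' @describeIn FretFit the recorded chains
#' @export
fitChains <- function(object) object@chains

#' Calibration of the kappa constants
#'
#' @slot kappa the inferred [KappaTable-class] (absolute units, or relative
#'   with the donor-channel donor constant fixed to 1).
#' @slot efrConstruct FRET efficiency of the tandem construct (relative
#'   mode; NA in absolute mode).
#' @slot se data.frame of uncertainties for the inferred constants.
#' @slot mode \code{"absolute"} or \code{"relative"}.
#' @slot scaleNote reminder that relative-mode Kd estimates are scaled by
#'   the reference constant.
#' @slot draws posterior draws (relative mode), columns named after the
#'   free constants.
#' @export
setClass("CalibrationResult",
         representation(kappa = "KappaTable", efrConstruct = "numeric",
                        se = "data.frame", mode = "character",
                        scaleNote = "character", draws = "matrix"))

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult (%s mode)\n", object@mode))
  print(object@kappa@kappa)
  if (!is.na(object@efrConstruct))
    cat(sprintf("  construct FRET efficiency: %.4g\n", object@efrConstruct))
  cat(" ", object@scaleNote, "\n")
})
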