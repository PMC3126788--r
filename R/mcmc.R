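# Metropolis-Hastings sampling of (Kd, E_fr): random-walk core, step-size
# tuning to the 40-60% acceptance band, burn-in detection, multi-chain
# convergence checks and posterior summaries.

# Generic d-dimensional Metropolis-Hastings random walk. logpost takes a
# numeric state vector; commit() is invoked after every accepted proposal
# (used to promote warm starts). stepSd is either a vector of independent
# Gaussian step SDs or a matrix L giving correlated increments L z,
# z ~ N(0, I) (proposal covariance L L'). Proposals outside the support
# are rejected through the prior's -Inf, which with a symmetric Gaussian
# proposal preserves detailed balance.
.mhChain <- function(logpost, init, nSteps, stepSd, seed = NULL,
                     commit = NULL) {
  d <- length(init)
  shaped <- is.matrix(stepSd)
  if (!is.null(seed)) set.seed(as.integer(seed))
  states <- matrix(NA_real_, nSteps, d)
  energies <- numeric(nSteps)
  accepted <- rep(NA, nSteps)
  lp <- logpost(init)
  if (!is.finite(lp))
    stop("initial state has -Inf posterior; choose a new start")
  if (!is.null(commit)) commit()
  states[1, ] <- init
  energies[1] <- -lp
  cur <- init
  for (j in seq_len(nSteps)[-1]) {
    prop <- if (shaped) cur + as.vector(stepSd %*% rnorm(d))
            else cur + rnorm(d, 0, stepSd)
    lpn <- logpost(prop)
    if (is.finite(lpn) && log(runif(1)) < lpn - lp) {
      cur <- prop
      lp <- lpn
      accepted[j] <- TRUE
      if (!is.null(commit)) commit()
    } else {
      accepted[j] <- FALSE
    }
    states[j, ] <- cur
    energies[j] <- -lp
  }
  list(states = states, energies = energies, accepted = accepted)
}

#' Run one Metropolis-Hastings chain over (log10 Kd, E_fr)
#'
#' Standard Metropolis-Hastings: proposals are independent Gaussian
#' increments in (log10 Kd, E_fr); a proposal with higher posterior is
#' always accepted, otherwise it is accepted with probability equal to
#' the posterior ratio (computed in log space). Rejected proposals repeat
#' the current state. Reproducible for a fixed seed.
#'
#' @param object a [FretSet-class].
#' @param kappa a [KappaTable-class].
#' @param prior a [FretPrior-class].
#' @param init numeric(2): initial \code{c(log10Kd, efr)}; must have
#'   finite posterior.
#' @param nSteps number of recorded states (>= 1), including the initial
#'   state.
#' @param proposal a [ProposalSpec-class].
#' @param seed integer seed.
#' @param noise optional noise scales as in [estimateNoise()].
#' @return A [FretChains-class] with a single chain (burn-in not yet
#'   detected).
#' @export
runChain <- function(object, kappa, prior, init, nSteps, proposal,
                     seed = 1L, noise = NULL) {
  stopifnot(is(proposal, "ProposalSpec"), nSteps >= 1)
  fac <- .posteriorFactory(object, kappa, prior, noise)
  res <- .mhChain(fac$logpost, init, nSteps,
                  c(proposal@stepLogKd, proposal@stepEfr),
                  seed = seed, commit = fac$commit)
  colnames(res$states) <- c("log10_kd", "efr")
  new("FretChains", states = list(res$states),
      energies = list(res$energies), accepted = list(res$accepted),
      burnIn = NA_integer_, proposal = proposal,
      seeds = as.integer(seed))
}

# one tuning pass over a generic target; returns the frozen step SDs
.tuneSteps <- function(logpost, init, stepSd, seed, commit = NULL,
                       blockSize = 100L, maxBlocks = 50L,
                       band = c(0.40, 0.60), stepCap = NULL) {
  set.seed(as.integer(seed))
  if (is.null(stepCap)) stepCap <- stepSd * 1e3
  cur <- init
  best <- stepSd
  bestDist <- Inf
  blocks <- 0L
  acc <- NA_real_
  repeat {
    blocks <- blocks + 1L
    res <- .mhChain(logpost, cur, blockSize, stepSd, seed = NULL,
                    commit = commit)
    cur <- res$states[blockSize, ]
    acc <- mean(res$accepted[-1])
    dist <- max(band[1] - acc, acc - band[2], 0)
    if (dist < bestDist) { bestDist <- dist; best <- stepSd }
    if (acc >= band[1] && acc <= band[2]) {
      # confirmation: a longer un-adapted stretch must also land in band
      conf <- .mhChain(logpost, cur, 3L * blockSize, stepSd, seed = NULL,
                       commit = commit)
      cur <- conf$states[3L * blockSize, ]
      accc <- mean(conf$accepted[-1])
      if (accc >= band[1] && accc <= band[2])
        return(list(stepSd = stepSd, acceptance = accc, blocks = blocks,
                    converged = TRUE, state = cur))
      acc <- accc
    }
    if (blocks >= maxBlocks) {
      if (acc > band[2] && all(stepSd >= stepCap))
        warning("acceptance band unreachable from above even at the step ",
                "cap (target may be flat); returning max-step proposal")
      else
        warning("step-size tuning did not settle in the 40-60% band; ",
                "returning the best proposal found")
      return(list(stepSd = best, acceptance = acc, blocks = blocks,
                  converged = FALSE, state = cur))
    }
    # multiplicative update toward 50% acceptance
    f <- min(3, max(1 / 3, acc / 0.5))
    stepSd <- if (is.matrix(stepSd)) stepSd * f
              else pmin(pmax(stepSd * f, 1e-8), stepCap)
  }
}

# Shared pipeline for the auxiliary samplers (calibration, apparent
# mode): scalar step tuning from a rough init, a pilot run to learn the
# posterior covariance, covariance-shaped proposals with the overall
# factor re-tuned and frozen, then several chains from overdispersed but
# posterior-scaled starts. Returns pooled post-burn-in draws plus
# per-coordinate PSRF.
.mhFitShaped <- function(logpost, init, nChains, nSteps, seed, stepSd0,
                         stepCap, disperse = 5) {
  d <- length(init)
  set.seed(as.integer(seed))
  tuned <- .tuneSteps(logpost, init, stepSd = stepSd0, seed = seed,
                      stepCap = stepCap)
  pilot <- .mhChain(logpost, tuned$state, 3000L, tuned$stepSd,
                    seed = seed + 5L)
  pilotDraws <- pilot$states[1501:3000, , drop = FALSE]
  cv <- stats::cov(pilotDraws) + diag(1e-10, d)
  L <- t(chol(cv)) * 2.4 / sqrt(d)
  tuned <- .tuneSteps(logpost, pilot$states[3000L, ], stepSd = L,
                      seed = seed + 6L, stepCap = stepCap)
  chains <- lapply(seq_len(nChains), function(i) {
    set.seed(seed + 40L + i)
    repeat {
      jit <- as.vector(tuned$state + disperse * (L %*% rnorm(d)))
      if (is.finite(logpost(jit))) break
    }
    .mhChain(logpost, jit, nSteps, tuned$stepSd, seed = seed + 10L + i)
  })
  bi <- vapply(chains, function(ch) .detectBurnInEnergy(ch$energies),
               integer(1))
  draws <- do.call(rbind, lapply(seq_along(chains), function(i) {
    s <- chains[[i]]$states
    s[seq.int(bi[i], nrow(s)), , drop = FALSE]
  }))
  psrf <- vapply(seq_len(d), function(p)
    .psrf(lapply(seq_along(chains), function(i) {
      s <- chains[[i]]$states
      s[seq.int(bi[i], nrow(s)), p]
    })), numeric(1))
  acc <- mean(vapply(chains, function(ch) mean(ch$accepted[-1]),
                     numeric(1)))
  list(draws = draws, psrf = psrf, stepSd = tuned$stepSd,
       acceptance = acc, burnIn = bi)
}

#' Tune the proposal step sizes to the 40-60% acceptance band
#'
#' Runs a pilot phase in 100-step blocks, multiplying both step SDs by a
#' factor that pushes the block acceptance rate toward 50%, until a block
#' (and a subsequent 300-step confirmation stretch without adaptation)
#' lands in the 40-60% band. Adaptation is frozen before any recorded
#' samples, preserving detailed balance for the recording phase. If the
#' band is unreachable within 50 blocks (e.g. a flat target accepts every
#' proposal at any step size), the best proposal found is returned with a
#' warning.
#'
#' @inheritParams runChain
#' @param init numeric(2): \code{c(log10Kd, efr)} starting point.
#' @param initialStep starting step SDs \code{c(log10Kd, efr)}.
#' @return A [ProposalSpec-class]; attributes \code{acceptance},
#'   \code{blocks}, \code{converged} and \code{state} (the final pilot
#'   state, a good chain start) record the tuning outcome.
#' @export
tuneStepSize <- function(object, kappa, prior, init, seed = 1L,
                         noise = NULL, initialStep = c(1, 0.1)) {
  fac <- .posteriorFactory(object, kappa, prior, noise)
  tuned <- .tuneSteps(fac$logpost, init, initialStep, seed,
                      commit = fac$commit,
                      stepCap = c(diff(prior@kdBounds) / 2, 0.5))
  out <- proposalSpec(tuned$stepSd[1], tuned$stepSd[2])
  attr(out, "acceptance") <- tuned$acceptance
  attr(out, "blocks") <- tuned$blocks
  attr(out, "converged") <- tuned$converged
  attr(out, "state") <- tuned$state
  out
}

# burn-in on a single energy trace
.detectBurnInEnergy <- function(e, window = 100L) {
  L <- length(e)
  if (L < 2L * window) stop("chain too short for burn-in detection")
  refIdx <- seq.int(L - floor(L / 4) + 1L, L)
  ref <- mean(e[refIdx])
  half <- as.integer(L %/% 2)
  for (t in seq_len(L - window + 1L)) {
    w <- e[t:(t + window - 1L)]
    if (abs(mean(w) - ref) <= 2 * sd(w)) {
      if (t > half)
        warning("chain energy only stabilizes in its second half; ",
                "capping burn-in at half the chain")
      return(min(as.integer(t), half))
    }
  }
  warning("no stationary window found; using half the chain as burn-in")
  half
}

#' Detect the burn-in index of a chain
#'
#' Returns the first index from which the running 100-state window mean
#' energy lies within two window standard deviations of the mean energy
#' over the final quarter of the chain; states before this index are
#' discarded from summaries. The index never exceeds half the chain;
#' pathological chains return half the length with a warning.
#'
#' @param chain a [FretChains-class] (all chains are processed) or a
#'   numeric energy vector.
#' @param window running-window width in states.
#' @return Integer burn-in index per chain. For a \code{FretChains}
#'   input the object is returned with its \code{burnIn} slot filled
#'   (use [burnIn()] to read it).
#' @export
detectBurnIn <- function(chain, window = 100L) {
  if (is.numeric(chain)) return(.detectBurnInEnergy(chain, window))
  stopifnot(is(chain, "FretChains"))
  chain@burnIn <- vapply(chain@energies, .detectBurnInEnergy,
                         integer(1), window = window)
  chain
}

# split-free Gelman-Rubin potential scale reduction factor, floored at 1
.psrf <- function(draws) {
  # draws: list of equal-length numeric vectors (>= 2 chains)
  n <- min(lengths(draws))
  x <- vapply(draws, function(d) tail(d, n), numeric(n))
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  if (W <= 0) return(1)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

#' Multi-chain convergence check
#'
#' Computes the potential scale reduction factor (PSRF, Gelman-Rubin) of
#' the post-burn-in log10(Kd) and efficiency draws across chains, and
#' checks that all pairwise post-burn-in interquartile ranges overlap.
#' Convergence passes when both PSRFs are below 1.1 and the IQRs overlap
#' (the stationary distributions of all walks coincide). The PSRF is
#' floored at 1.
#'
#' @param chains a [FretChains-class] with at least 2 chains; burn-in
#'   must have been detected (or is detected here).
#' @return list with elements \code{psrf} (named numeric), \code{iqrOverlap}
#'   (logical) and \code{pass}.
#' @export
checkConvergence <- function(chains) {
  stopifnot(is(chains, "FretChains"))
  if (nChains(chains) < 2) stop("need at least 2 chains")
  if (anyNA(chains@burnIn)) chains <- detectBurnIn(chains)
  post <- lapply(seq_len(nChains(chains)), function(i) {
    s <- chains@states[[i]]
    s[seq.int(chains@burnIn[i], nrow(s)), , drop = FALSE]
  })
  pn <- colnames(chains@states[[1]])
  psrf <- vapply(seq_along(pn), function(p)
    .psrf(lapply(post, function(s) s[, p])), numeric(1))
  names(psrf) <- pn
  overlap <- TRUE
  for (p in seq_along(pn)) {
    qs <- vapply(post, function(s) quantile(s[, p], c(0.25, 0.75),
                                            names = FALSE), numeric(2))
    nc <- ncol(qs)
    for (a in seq_len(nc - 1)) for (b in seq.int(a + 1, nc))
      if (qs[1, a] > qs[2, b] || qs[1, b] > qs[2, a]) overlap <- FALSE
  }
  list(psrf = psrf, iqrOverlap = overlap,
       pass = all(psrf < 1.1) && overlap)
}

# pooled post-burn-in draws as a matrix
.pooledDraws <- function(chains) {
  if (anyNA(chains@burnIn)) chains <- detectBurnIn(chains)
  do.call(rbind, lapply(seq_len(nChains(chains)), function(i) {
    s <- chains@states[[i]]
    s[seq.int(chains@burnIn[i], nrow(s)), , drop = FALSE]
  }))
}

# population (1/N) standard deviation: summaries describe the sampled
# posterior itself, and this matches cv arithmetic on tiny draw sets
.sdPop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize the posterior from pooled chains
#'
#' Pools the post-burn-in draws of all chains and reports, for Kd (on the
#' natural molar scale) and the efficiency: posterior mean, SD, coefficient
#' of variation (SD/mean, the relative-uncertainty measure), and the 5th,
#' 50th and 95th percentiles. When the generating truth is supplied, the
#' error of the Kd estimate is \code{log10(mean(Kd draws) / true Kd)} (a
#' perfect estimate scores 0) and the efficiency error is the plain
#' difference of means.
#'
#' @param chains a [FretChains-class].
#' @param truth optional list/vector with elements \code{Kd} (molar) and
#'   \code{efr}.
#' @return data.frame with rows \code{Kd} and \code{E_fr}.
#' @export
summarizePosterior <- function(chains, truth = NULL) {
  stopifnot(is(chains, "FretChains"))
  draws <- .pooledDraws(chains)
  if (nrow(draws) == 0) stop("no post-burn-in draws to summarize")
  kd <- 10^draws[, "log10_kd"]
  ef <- draws[, "efr"]
  summ <- function(x) {
    q <- quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    c(mean = mean(x), sd = .sdPop(x), cv = .sdPop(x) / mean(x),
      q05 = q[1], q50 = q[2], q95 = q[3])
  }
  out <- as.data.frame(rbind(Kd = summ(kd), E_fr = summ(ef)))
  out$error <- NA_real_
  if (!is.null(truth)) {
    out["Kd", "error"] <- log10(out["Kd", "mean"] / truth[["Kd"]])
    out["E_fr", "error"] <- out["E_fr", "mean"] - truth[["efr"]]
  }
  out$n_draws <- nrow(draws)
  out
}

# merge single-chain FretChains objects
.bindChains <- function(chainList, proposal) {
  new("FretChains",
      states = lapply(chainList, function(c) c@states[[1]]),
      energies = lapply(chainList, function(c) c@energies[[1]]),
      accepted = lapply(chainList, function(c) c@accepted[[1]]),
      burnIn = rep(NA_integer_, length(chainList)),
      proposal = proposal,
      seeds = vapply(chainList, function(c) c@seeds, integer(1)))
}

# draw an in-support chain start from the prior (overdispersed inits)
.drawInit <- function(prior) {
  lkd <- runif(1, prior@kdBounds[1], prior@kdBounds[2])
  ef <- if (is.na(prior@efrMean)) runif(1) else {
    repeat {
      x <- rnorm(1, prior@efrMean, prior@efrSd)
      if (x >= 0 && x <= 1) break
    }
    x
  }
  c(lkd, ef)
}

#' Fit (Kd, E_fr) by multi-chain Metropolis-Hastings
#'
#' The full inference pipeline: tune the proposal step sizes on a pilot
#' phase, run several independent chains from overdispersed starts drawn
#' from the prior, detect each chain's burn-in, check multi-chain
#' convergence, and summarize the pooled posterior.
#'
#' @param object a [FretSet-class].
#' @param kappa a [KappaTable-class].
#' @param prior a [FretPrior-class].
#' @param nChains number of chains (default 3).
#' @param nSteps recorded steps per chain (default 20000).
#' @param seed master integer seed; chain seeds are derived from it.
#' @param noise optional noise scales as in [estimateNoise()].
#' @param truth optional truth passed to [summarizePosterior()].
#' @return A [FretFit-class].
#' @examples
#' \donttest{
#' fs <- simulateFretData(1e-6, 0.4, c(0.2, 1, 5) * 1e-6,
#'                        c(0.2, 1, 5) * 1e-6, n = 10, r = 0.05, seed = 7)
#' fit <- fitKd(fs, defaultKappa(), nSteps = 4000, seed = 7)
#' posteriorSummary(fit)
#' }
#' @export
fitKd <- function(object, kappa, prior = fretPrior(), nChains = 3L,
                  nSteps = 20000L, seed = 1L, noise = NULL, truth = NULL) {
  seed <- as.integer(seed)
  set.seed(seed)
  repeat {
    init0 <- .drawInit(prior)
    if (is.finite(logPosterior(object, 10^init0[1], init0[2], kappa,
                               prior, noise))) break
  }
  prop <- tuneStepSize(object, kappa, prior, init0, seed = seed + 1L,
                       noise = noise)
  chainList <- vector("list", nChains)
  for (i in seq_len(nChains)) {
    set.seed(seed + 100L + i)
    repeat {
      init <- .drawInit(prior)
      lp <- logPosterior(object, 10^init[1], init[2], kappa, prior, noise)
      if (is.finite(lp)) break
    }
    chainList[[i]] <- runChain(object, kappa, prior, init, nSteps, prop,
                               seed = seed + 200L + i, noise = noise)
  }
  chains <- detectBurnIn(.bindChains(chainList, prop))
  conv <- checkConvergence(chains)
  if (!conv$pass)
    warning("chains did not pass the convergence check (PSRF/IQR overlap)")
  new("FretFit", chains = chains,
      summary = summarizePosterior(chains, truth = truth),
      convergence = conv, proposal = prop)
}
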