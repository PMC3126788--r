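# File formats and the experiment runner. Measurements travel as a wide
# CSV (one row per replicate, one column per channel), kappa tables as a
# small YAML config; the experiment runner reproduces the simulation
# studies (noise, data quantity, concentration design, ratio, prior) at
# configurable scale.

#' Read a three-cube measurements CSV
#'
#' Expected header: \code{sample_id, replicate, I_D, I_A, I_F}; optional
#' per-sample truth columns \code{D0} and \code{A0}; comment lines start
#' with \code{#}. Replicate counts must agree across the three channels
#' within every sample (an NA in one channel breaks the balance and is
#' reported).
#'
#' @param path CSV file path.
#' @param units \code{"M"} (default) or \code{"uM"}: units of the optional
#'   concentration columns, converted to molar on read.
#' @return A [FretSet-class].
#' @export
readFretData <- function(path, units = c("M", "uM")) {
  units <- match.arg(units)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no samples: the measurements file is empty")
  need <- c("sample_id", "replicate", "I_D", "I_A", "I_F")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  for (cc in c("I_D", "I_A", "I_F")) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) &
                     !is.na(df[[cc]]))[1]
      stop(sprintf("non-numeric intensity in column %s at data row %d", cc,
                   if (is.na(bad)) 1L else bad))
    }
  }
  ids <- unique(df$sample_id)
  for (s in ids) {
    sub <- df[df$sample_id == s, ]
    cnt <- c(sum(!is.na(sub$I_D)), sum(!is.na(sub$I_A)),
             sum(!is.na(sub$I_F)))
    if (length(unique(cnt)) != 1)
      stop(sprintf(
        "sample '%s': replicate counts differ across channels (%s)", s,
        paste(cnt, collapse = "/")))
  }
  nmax <- max(table(df$sample_id))
  pad <- function(x) c(x, rep(NA_real_, nmax - length(x)))
  dn <- vapply(ids, function(s) pad(df$I_D[df$sample_id == s]),
               numeric(nmax))
  ac <- vapply(ids, function(s) pad(df$I_A[df$sample_id == s]),
               numeric(nmax))
  fr <- vapply(ids, function(s) pad(df$I_F[df$sample_id == s]),
               numeric(nmax))
  dn <- matrix(dn, nrow = nmax, dimnames = list(NULL, ids))
  ac <- matrix(ac, nrow = nmax, dimnames = list(NULL, ids))
  fr <- matrix(fr, nrow = nmax, dimnames = list(NULL, ids))
  sampleData <- NULL
  if (all(c("D0", "A0") %in% colnames(df))) {
    scl <- if (units == "uM") 1e-6 else 1
    sampleData <- data.frame(
      D0 = vapply(ids, function(s) df$D0[df$sample_id == s][1],
                  numeric(1)) * scl,
      A0 = vapply(ids, function(s) df$A0[df$sample_id == s][1],
                  numeric(1)) * scl)
  }
  FretSet(donor = dn, acceptor = ac, fret = fr, sampleData = sampleData)
}

#' Write a FretSet as a measurements CSV
#'
#' Writes the wide replicate-per-row layout read by [readFretData()],
#' with full \code{%.17g} precision so a write/read cycle reproduces the
#' numbers bit-exactly, and a provenance comment header (units and, for
#' simulated data, the generating configuration).
#'
#' @param object a [FretSet-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeFretData <- function(object, path) {
  stopifnot(is(object, "FretSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fretBayes three-cube measurements (units: M, intensities AU)",
             con)
  sim <- S4Vectors::metadata(object)$simulation
  if (!is.null(sim))
    writeLines(sprintf(
      "# simulated: Kd=%.6g M, efr=%.3g, n=%d, r=%.3g, seed=%d",
      sim$Kd, sim$efr, sim$n, sim$r, sim$seed), con)
  writeLines("sample_id,replicate,I_D,I_A,I_F", con)
  nrep <- SummarizedExperiment::colData(object)$n_replicates
  dn <- SummarizedExperiment::assay(object, "donor")
  ac <- SummarizedExperiment::assay(object, "acceptor")
  fr <- SummarizedExperiment::assay(object, "fret")
  for (j in seq_len(ncol(object))) {
    for (i in seq_len(nrep[j])) {
      writeLines(sprintf("%s,%d,%.17g,%.17g,%.17g",
                         colnames(object)[j], i, dn[i, j], ac[i, j],
                         fr[i, j]), con)
    }
  }
  invisible(path)
}

#' Read / write a kappa-table config
#'
#' The kappa constants are stored as a small YAML file with keys
#' \code{kappa_D}, \code{kappa_A}, \code{kappa_F} (each three values in
#' channel order donor, acceptor, FRET).
#'
#' @param path YAML file path.
#' @return [readKappa()]: a [KappaTable-class]; [writeKappa()]:
#'   invisibly, \code{path}.
#' @export
readKappa <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("kappa_D", "kappa_A", "kappa_F")
  if (!all(need %in% names(y)))
    stop("kappa config must contain kappa_D, kappa_A, kappa_F")
  KappaTable(as.numeric(y$kappa_D), as.numeric(y$kappa_A),
             as.numeric(y$kappa_F))
}

#' @rdname readKappa
#' @param kappa a [KappaTable-class].
#' @export
writeKappa <- function(kappa, path) {
  stopifnot(is(kappa, "KappaTable"))
  yaml::write_yaml(list(channels = c("donor", "acceptor", "fret"),
                        kappa_D = as.numeric(kappaD(kappa)),
                        kappa_A = as.numeric(kappaA(kappa)),
                        kappa_F = as.numeric(kappaF(kappa))), path)
  invisible(path)
}

# one-dataset, one-walk fit used by the replicate studies (the sweeps
# analyze each dataset with a single tuned walk)
.singleFit <- function(object, kappa, prior, nSteps, seed, truth = NULL,
                       noise = NULL) {
  set.seed(as.integer(seed))
  repeat {
    init <- .drawInit(prior)
    if (is.finite(logPosterior(object, 10^init[1], init[2], kappa, prior,
                               noise))) break
  }
  prop <- tuneStepSize(object, kappa, prior, init, seed = seed + 1L,
                       noise = noise)
  st0 <- attr(prop, "state")
  ch <- runChain(object, kappa, prior, st0, nSteps, prop,
                 seed = seed + 2L, noise = noise)
  ch <- detectBurnIn(ch)
  list(summary = summarizePosterior(ch, truth = truth), chains = ch)
}

#' Run a named simulation study
#'
#' Reproduces the parameter-recovery studies at configurable scale:
#' \describe{
#'   \item{noise_sweep}{relative noise r in {0.01, 0.05, 0.10}; 3 cells at
#'     0.2/1/5 uM, 10 measurements/cell/channel.}
#'   \item{nmeas_sweep}{measurements per cell per channel n in
#'     {3, 10, 50} at 5\% noise.}
#'   \item{concentration_variation}{one cell, three identical cells, and
#'     two- or three-cell designs with varied concentrations (3\% noise):
#'     reports the spread of log10 Kd and the |rank correlation| between
#'     log10 Kd and efficiency draws (the ridge signature).}
#'   \item{plateau}{equal concentrations far below (nM), near (uM) and far
#'     above (mM) the true Kd; reports Kd posterior percentiles.}
#'   \item{ratio_sweep}{donor:acceptor ratio in {1, 3, 10} at n = 50,
#'     3\% noise; reports the Kd cv.}
#'   \item{prior_benefit}{uniform vs Gaussian(0.45, sd 0.15) efficiency
#'     prior on matched datasets with n = 3 and n = 10.}
#' }
#' Every study simulates \code{nDatasets} replicate datasets per condition
#' (truth Kd = 1 uM, efficiency 0.4) and analyzes each with one tuned
#' Metropolis-Hastings walk of \code{nSteps} recorded steps.
#'
#' @param study study name (see above).
#' @param nDatasets replicate datasets per condition (default 10; the
#'   original studies used 50).
#' @param nSteps recorded steps per walk.
#' @param seed master integer seed; per-dataset and per-walk seeds are
#'   derived from it.
#' @param kappa a [KappaTable-class].
#' @param outDir optional directory: writes \code{<study>_results.csv}
#'   and \code{<study>_config.yaml}.
#' @return data.frame of per-condition, per-dataset summaries; the run
#'   configuration is attached as \code{attr(, "config")}.
#' @export
runExperiment <- function(study = c("noise_sweep", "nmeas_sweep",
                                    "concentration_variation", "plateau",
                                    "ratio_sweep", "prior_benefit"),
                          nDatasets = 10L, nSteps = 5000L, seed = 1L,
                          kappa = defaultKappa(), outDir = NULL) {
  study <- match.arg(study)
  seed <- as.integer(seed)
  truth <- list(Kd = 1e-6, efr = 0.4)
  base <- c(0.2, 1, 5) * 1e-6
  prior <- fretPrior()
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  runCase <- function(condLabel, condIdx, ds, D0, A0, n, r,
                      prior_ = prior, extra = NULL) {
    dseed <- seed + 10000L * condIdx + 100L * ds
    fs <- simulateFretData(truth$Kd, truth$efr, D0, A0, n = n, r = r,
                           kappa = kappa, seed = dseed)
    fit <- .singleFit(fs, kappa, prior_, nSteps, seed = dseed + 50L,
                      truth = truth)
    s <- fit$summary
    df <- data.frame(condition = condLabel, dataset = ds,
                     kd_mean = s["Kd", "mean"], kd_cv = s["Kd", "cv"],
                     kd_sd = s["Kd", "sd"],
                     kd_q05 = s["Kd", "q05"], kd_q95 = s["Kd", "q95"],
                     kd_error = s["Kd", "error"],
                     efr_mean = s["E_fr", "mean"], efr_sd = s["E_fr", "sd"],
                     efr_cv = s["E_fr", "cv"])
    if (!is.null(extra)) {
      draws <- .pooledDraws(fit$chains)
      for (nm in names(extra)) df[[nm]] <- extra[[nm]](draws)
    }
    rows[[length(rows) + 1L]] <<- df
    fit
  }

  if (study == "noise_sweep") {
    for (ci in seq_along(c(0.01, 0.05, 0.10))) {
      r <- c(0.01, 0.05, 0.10)[ci]
      for (ds in seq_len(nDatasets))
        runCase(sprintf("r=%.2f", r), ci, ds, base, base, n = 10, r = r)
    }
  } else if (study == "nmeas_sweep") {
    for (ci in seq_along(c(3, 10, 50))) {
      n <- c(3, 10, 50)[ci]
      for (ds in seq_len(nDatasets))
        runCase(sprintf("n=%d", n), ci, ds, base, base, n = n, r = 0.05)
    }
  } else if (study == "concentration_variation") {
    designs <- list(single = 1e-6, three_identical = rep(1e-6, 3),
                    pair_low = c(0.5, 1) * 1e-6,
                    pair_high = c(1, 5) * 1e-6,
                    three_varied = c(0.5, 1, 5) * 1e-6)
    ridge <- list(
      log10kd_sd = function(d) sd(d[, "log10_kd"]),
      ridge_cor = function(d) {
        if (sd(d[, "efr"]) == 0 || sd(d[, "log10_kd"]) == 0) return(NA_real_)
        abs(cor(d[, "log10_kd"], d[, "efr"], method = "spearman"))
      })
    for (ci in seq_along(designs)) {
      cc <- designs[[ci]]
      for (ds in seq_len(nDatasets))
        runCase(names(designs)[ci], ci, ds, cc, cc, n = 10, r = 0.03,
                extra = ridge)
    }
  } else if (study == "plateau") {
    scales <- c(low_nM = 1e-9, mid_uM = 1e-6, high_mM = 1e-3)
    for (ci in seq_along(scales)) {
      cc <- c(0.2, 1, 5) * scales[ci]
      for (ds in seq_len(nDatasets))
        runCase(names(scales)[ci], ci, ds, cc, cc, n = 10, r = 0.05)
    }
  } else if (study == "ratio_sweep") {
    for (ci in seq_along(c(1, 3, 10))) {
      ratio <- c(1, 3, 10)[ci]
      for (ds in seq_len(nDatasets))
        runCase(sprintf("ratio=%g", ratio), ci, ds, base, base / ratio,
                n = 50, r = 0.03)
    }
  } else if (study == "prior_benefit") {
    pri <- list(uniform = fretPrior(),
                gaussian = fretPrior(efr = c(0.45, 0.15)))
    ci <- 0L
    for (n in c(3, 10)) {
      for (p in seq_along(pri)) {
        ci <- ci + 1L
        for (ds in seq_len(nDatasets)) {
          # matched datasets: the dataset seed depends on n and ds only,
          # so both priors see identical data
          dseed <- seed + 10000L * n + 100L * ds
          fs <- simulateFretData(truth$Kd, truth$efr, base, base, n = n,
                                 r = 0.05, kappa = kappa, seed = dseed)
          fit <- .singleFit(fs, kappa, pri[[p]], nSteps,
                            seed = dseed + 50L + p, truth = truth)
          s <- fit$summary
          addRow(condition = sprintf("n=%d_%s", n, names(pri)[p]),
                 dataset = ds, kd_mean = s["Kd", "mean"],
                 kd_cv = s["Kd", "cv"], kd_sd = s["Kd", "sd"],
                 kd_q05 = s["Kd", "q05"], kd_q95 = s["Kd", "q95"],
                 kd_error = s["Kd", "error"],
                 efr_mean = s["E_fr", "mean"], efr_sd = s["E_fr", "sd"],
                 efr_cv = s["E_fr", "cv"])
        }
      }
    }
  }

  out <- do.call(rbind, rows)
  cfg <- list(study = study, nDatasets = nDatasets, nSteps = nSteps,
              seed = seed, truth = truth, kappa = kappa@kappa)
  attr(out, "config") <- cfg
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(outDir, paste0(study, "_results.csv")),
              row.names = FALSE)
    yaml::write_yaml(list(study = study, nDatasets = nDatasets,
                          nSteps = nSteps, seed = seed,
                          truth = truth,
                          kappa = apply(kappa@kappa, 2, as.numeric,
                                        simplify = FALSE)),
                     file.path(outDir, paste0(study, "_config.yaml")))
  }
  out
}
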