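#' Solve the bimolecular binding equilibrium
#'
#' For totals \code{D0 = [D] + [DA]} and \code{A0 = [A] + [DA]} and
#' dissociation constant \code{Kd = [D][A]/[DA]}, the complex concentration
#' is the physically valid (smaller) root of
#' \code{DA^2 - (D0 + A0 + Kd) DA + D0 A0 = 0}. The root is evaluated in
#' the rationalized form \code{2 D0 A0 / (b + sqrt(b^2 - 4 D0 A0))} with
#' \code{b = D0 + A0 + Kd}, which stays accurate when \code{Kd >> D0 + A0}
#' (the weak-binding regime where the naive formula cancels
#' catastrophically). Tiny negative free concentrations from roundoff are
#' clamped to zero.
#'
#' @param D0,A0 total donor and acceptor concentrations, molar, >= 0.
#' @param Kd dissociation constant, molar, > 0.
#' @return Named numeric vector with components \code{D0}, \code{A0},
#'   \code{D}, \code{A}, \code{DA} (all molar).
#' @examples
#' solveEquilibrium(1e-6, 1e-6, 1e-6)  # DA = (3 - sqrt(5))/2 uM
#' @export
solveEquilibrium <- function(D0, A0, Kd) {
  if (!is.finite(Kd) || Kd <= 0) stop("Kd must be a positive number")
  if (D0 < 0 || A0 < 0) stop("total concentrations must be >= 0")
  b <- D0 + A0 + Kd
  disc <- b * b - 4 * D0 * A0
  if (disc < 0) disc <- 0
  DA <- if (b > 0) 2 * D0 * A0 / (b + sqrt(disc)) else 0
  tol <- 1e-15 * max(D0, A0)
  D <- D0 - DA
  A <- A0 - DA
  if (D < 0 && D > -tol) D <- 0
  if (A < 0 && A > -tol) A <- 0
  c(D0 = D0, A0 = A0, D = D, A = A, DA = DA)
}

#' Spectral mixing matrix of the three-cube model
#'
#' Builds the 3 x 3 matrix \code{M} that maps the species concentrations
#' \code{([D], [A], [DA])} to the predicted intensities in the donor,
#' acceptor and FRET channels. The free-donor and free-acceptor columns
#' are the corresponding kappa constants; the complex column combines
#' donor emission attenuated by FRET, full acceptor emission, and
#' FRET-sensitized emission:
#' \code{kappa_D (1 - E_fr) + kappa_A + kappa_F E_fr}.
#'
#' @param kappa a [KappaTable-class].
#' @param efr intrinsic FRET efficiency in [0, 1].
#' @return 3 x 3 numeric matrix, rows = channels, columns
#'   \code{c("D", "A", "DA")}.
#' @export
mixingMatrix <- function(kappa, efr) {
  stopifnot(is(kappa, "KappaTable"))
  if (!is.finite(efr) || efr < 0 || efr > 1)
    stop("efr must lie in [0, 1]")
  k <- kappa@kappa
  m <- cbind(D = k[, "D"], A = k[, "A"],
             DA = k[, "D"] * (1 - efr) + k[, "A"] + k[, "F"] * efr)
  rownames(m) <- rownames(k)
  m
}

#' Predict noiseless three-cube intensities
#'
#' Solves the binding equilibrium for the species concentrations and
#' applies the spectral mixing matrix. Equivalently (and as computed
#' internally): \code{I = kappa_D D0 + kappa_A A0 + (kappa_F - kappa_D)
#' E_fr [DA]}, channel-wise.
#'
#' @inheritParams solveEquilibrium
#' @param efr intrinsic FRET efficiency in [0, 1].
#' @param kappa a [KappaTable-class].
#' @return Named numeric vector \code{c(I_D, I_A, I_F)} of predicted
#'   intensities (arbitrary units, nonnegative).
#' @examples
#' predictIntensities(1e-6, 1e-6, Kd = 1e-6, efr = 0.4, defaultKappa())
#' @export
predictIntensities <- function(D0, A0, Kd, efr, kappa) {
  stopifnot(is(kappa, "KappaTable"))
  if (!is.finite(efr) || efr < 0 || efr > 1)
    stop("efr must lie in [0, 1]")
  eq <- solveEquilibrium(D0, A0, Kd)
  k <- kappa@kappa
  I <- k[, "D"] * D0 + k[, "A"] * A0 + (k[, "F"] - k[, "D"]) * efr * eq["DA"]
  names(I) <- c("I_D", "I_A", "I_F")
  I
}
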