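#' Polarization anisotropy surface
#'
#' Computes \eqn{r(\lambda, t) = (\Delta A_\parallel - \Delta A_\perp) /
#' (\Delta A_\parallel + 2 \Delta A_\perp)} from a parallel/perpendicular
#' pair on identical grids. Where the isotropic denominator falls below
#' \code{threshold} (isosbestic points, bleach cancellation) the anisotropy
#' diverges and the cell is masked.
#'
#' @param par,perp \linkS4class{TAMatrix} at parallel and perpendicular
#'   pump-probe polarization, identical grids.
#' @param threshold denominator magnitude below which cells are masked, OD
#'   (default 1 mOD).
#' @return a \linkS4class{TAMatrix} holding r (dimensionless, tagged
#'   "unpolarized").
#' @export
anisotropySurface <- function(par, perp, threshold = 1e-3) {
    .checkSameGrid(par@wavelengths, perp@wavelengths)
    .checkSameGrid(par@times, perp@times, "time")
    den <- par@values + 2 * perp@values
    bad <- par@mask | perp@mask | abs(den) < threshold
    r <- matrix(NA_real_, nrow(den), ncol(den))
    r[!bad] <- (par@values[!bad] - perp@values[!bad]) / den[!bad]
    taMatrix(par@wavelengths, par@times, r, polarization = "unpolarized",
             mask = bad, meta = list(quantity = "anisotropy",
                                     threshold = threshold))
}

#' Magic-angle reconstruction from a polarized pair
#'
#' \eqn{(\Delta A_\parallel + 2\Delta A_\perp)/3}: the isotropic signal,
#' equal to a measurement at the magic angle (54.71 deg) and free of
#' photoselection effects.
#'
#' @inheritParams anisotropySurface
#' @return a \linkS4class{TAMatrix} tagged "magic".
#' @export
magicAngle <- function(par, perp) {
    .checkSameGrid(par@wavelengths, perp@wavelengths)
    .checkSameGrid(par@times, perp@times, "time")
    taMatrix(par@wavelengths, par@times,
             (par@values + 2 * perp@values) / 3, polarization = "magic",
             mask = par@mask | perp@mask)
}

#' Theoretical photoselection anisotropy for a dipole pair
#'
#' For pump and probe transition dipoles at mutual angle theta,
#' \eqn{r = 0.4\,P_2(\cos\theta) = 0.2\,(3\cos^2\theta - 1)}; bounded in
#' [-0.2, 0.4] and zero at the magic angle 54.71 deg.
#'
#' @param thetaDeg angle between the transition dipoles, degrees.
#' @return anisotropy value(s).
#' @examples
#' theoreticalAnisotropy(c(0, 54.71, 90))
#' @export
theoreticalAnisotropy <- function(thetaDeg) {
    0.2 * (3 * cos(thetaDeg * pi / 180)^2 - 1)
}

#' Population- and extinction-weighted mean anisotropy
#'
#' When several species (or several probe transitions) with equal band
#' shapes overlap, the observed anisotropy is the weighted mean of the
#' individual anisotropies with weights = population x extinction.
#'
#' @param r anisotropies of the components.
#' @param weights nonnegative weights (populations x extinction), not all
#'   zero.
#' @return weighted mean anisotropy.
#' @examples
#' averagedAnisotropy(c(0.16, -0.12), c(1, 1))  # 0.02
#' @export
averagedAnisotropy <- function(r, weights = rep(1, length(r))) {
    if (any(weights < 0) || sum(weights) == 0)
        stop("weights must be nonnegative and not all zero")
    sum(weights * r) / sum(weights)
}

#' Fit an anisotropy decay with fixed rate constants
#'
#' Linear amplitude fit of an r(t) trace on the IRF-convolved exponential
#' basis with the rate constants held fixed (typically those of the
#' magic-angle global fit).
#'
#' @param trace numeric r(t) values.
#' @param times time grid, seconds (or unit strings).
#' @param basis a \linkS4class{KineticBasis} of fixed rates.
#' @param irfObj an \linkS4class{IRF}.
#' @return list with \code{amplitudes}, \code{fitted}, \code{residuals}
#'   and \code{chisq}.
#' @export
fitAnisotropyDecay <- function(trace, times, basis, irfObj) {
    times <- asSeconds(times)
    ok <- is.finite(trace)
    if (sum(ok) < length(basis@rates))
        stop("fewer finite points than components")
    F <- .designMatrix(times, basis, irfObj)
    a <- qr.coef(qr(F[ok, , drop = FALSE]), trace[ok])
    fitted <- as.vector(F %*% a)
    res <- trace - fitted
    list(amplitudes = a, fitted = fitted, residuals = res,
         chisq = sum(res[ok]^2))
}
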