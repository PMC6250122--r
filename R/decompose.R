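#' Construct a BasisSet of species spectra
#'
#' @param wavelengths grid in nm, ascending.
#' @param spectra matrix (wavelengths x species) with named columns, or a
#'   named list of numeric spectra.
#' @return a \linkS4class{BasisSet}.
#' @export
basisSet <- function(wavelengths, spectra) {
    if (is.list(spectra))
        spectra <- do.call(cbind, spectra)
    new("BasisSet", wavelengths = as.numeric(wavelengths),
        spectra = as.matrix(spectra))
}

#' Condition number of a basis set
#' @param b a \linkS4class{BasisSet}.
#' @return ratio of largest to smallest singular value of the spectra.
#' @export
basisCondition <- function(b) {
    d <- svd(b@spectra, nu = 0, nv = 0)$d
    d[1] / d[length(d)]
}

#' Decompose spectra into mole fractions over species basis spectra
#'
#' Solves, for each time point (matrix column) or each spectrum of a
#' sequence, the linear least-squares problem expressing the measured
#' spectrum as a combination of known species spectra, and normalizes the
#' coefficients by the total species amount. The per-point residual norm
#' and the deviation of the species sum from 1 are reported as diagnostics
#' -- physical reasonability (sum constant at 1) is checked, never imposed.
#'
#' @param x a \linkS4class{TAMatrix}, or a matrix of spectra (wavelengths x
#'   observations) together with \code{wl}.
#' @param basis a \linkS4class{BasisSet} (resampled onto the data grid by
#'   linear interpolation if the grids differ).
#' @param mode "unconstrained" (ordinary least squares, the default) or
#'   "nonnegative" (Lawson-Hanson NNLS via \code{pracma::lsqnonneg}).
#' @param wl wavelength grid when \code{x} is a bare matrix.
#' @param index time points / pulse indices for the observations.
#' @param total normalization: total species amount. Default is the
#'   coefficient sum of the first observation (e.g. the fitted dark-state
#'   amplitude of a fresh sample); pass 1 to keep raw coefficients.
#' @param conditionLimit error above this basis condition number; a warning
#'   is issued above sqrt of it.
#' @param conservedSpecies names of the species whose fractions should sum
#'   to 1 (the mass-conservation diagnostic); default all. Species on an
#'   arbitrary scale (e.g. an unidentified photoproduct) are excluded here.
#' @return a \linkS4class{MoleFractionProfile}.
#' @export
decomposeSpectra <- function(x, basis, mode = c("unconstrained", "nonnegative"),
                             wl = NULL, index = NULL, total = NULL,
                             conditionLimit = 1e6,
                             conservedSpecies = speciesNames(basis)) {
    mode <- match.arg(mode)
    if (is(x, "TAMatrix")) {
        wl <- x@wavelengths
        if (is.null(index)) index <- x@times
        Y <- x@values
        Y[x@mask] <- NA
    } else {
        Y <- as.matrix(x)
        if (is.null(wl)) stop("give wl for a bare spectra matrix")
        if (is.null(index)) index <- seq_len(ncol(Y))
    }
    lo <- max(min(wl), min(basis@wavelengths))
    hi <- min(max(wl), max(basis@wavelengths))
    if (lo >= hi) stop("empty overlap between data and basis wavelength grids")
    keep <- wl >= lo & wl <= hi
    S <- apply(basis@spectra, 2, function(s)
        stats::approx(basis@wavelengths, s, xout = wl[keep])$y)
    cn <- { d <- svd(S, nu = 0, nv = 0)$d; d[1] / d[length(d)] }
    if (cn > conditionLimit)
        stop(sprintf("ill-conditioned basis: condition number %.3g", cn))
    if (cn > sqrt(conditionLimit))
        warning(sprintf("basis condition number is high: %.3g", cn))
    n <- ncol(Y)
    coefs <- matrix(NA_real_, n, ncol(S),
                    dimnames = list(NULL, colnames(basis@spectra)))
    rn <- numeric(n)
    for (j in seq_len(n)) {
        y <- Y[keep, j]
        ok <- is.finite(y)
        Sj <- S[ok, , drop = FALSE]
        cf <- if (mode == "nonnegative")
            pracma::lsqnonneg(Sj, y[ok])$x
        else qr.coef(qr(Sj), y[ok])
        coefs[j, ] <- cf
        rn[j] <- sqrt(sum((y[ok] - Sj %*% cf)^2))
    }
    cons <- intersect(conservedSpecies, colnames(coefs))
    if (!length(cons)) stop("no conserved species in the basis")
    if (is.null(total)) total <- sum(coefs[1, cons])
    if (!is.finite(total) || total == 0)
        stop("cannot normalize: total species amount is 0")
    frac <- coefs / total
    new("MoleFractionProfile", index = as.numeric(index), fractions = frac,
        residualNorm = rn,
        sumDeviation = rowSums(frac[, cons, drop = FALSE]) - 1)
}

#' Shift a spectrum along the wavelength axis
#'
#' Returns the spectrum resampled so a feature at lambda appears at
#' lambda + shift (positive = redshift). Points that would come from
#' outside the original grid are NA.
#'
#' @param spec numeric spectrum.
#' @param wl wavelength grid, nm.
#' @param shift shift in nm.
#' @return shifted spectrum on the same grid.
#' @examples
#' wl <- 340:820
#' s <- exp(-((wl - 585) / 30)^2)
#' wl[which.max(shiftSpectrum(s, wl, 39))]  # 624
#' @export
shiftSpectrum <- function(spec, wl, shift) {
    if (abs(shift) >= diff(range(wl)))
        stop("shift exceeds the grid span")
    if (shift == 0) return(spec)
    out <- stats::splinefun(wl + shift, spec, method = "fmm")(wl)
    out[wl < min(wl) + shift | wl > max(wl) + shift] <- NA
    out
}

#' Henderson-Hasselbalch pocket pH
#'
#' Local pH of the chromophore binding pocket from the concentration ratio
#' of the deprotonated (base, e.g. the flavin anion radical) to the
#' protonated (acid, neutral radical) form:
#' pH = pKa + log10(base/acid).
#'
#' @param ratioBaseToAcid concentration ratio base/acid, > 0.
#' @param pKa acid dissociation constant of the pair.
#' @return pH estimate.
#' @examples
#' pocketPH(10, 8)  # 9
#' @export
pocketPH <- function(ratioBaseToAcid, pKa) {
    if (!is.finite(ratioBaseToAcid) || ratioBaseToAcid <= 0)
        stop("ratio must be positive")
    pKa + log10(ratioBaseToAcid)
}
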