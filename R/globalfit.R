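#' Construct an IRF
#'
#' @param center temporal center mu (seconds or unit string).
#' @param width Gaussian sigma (seconds or unit string). Give the FWHM via
#'   \code{fwhm} instead if preferred.
#' @param fwhm optional FWHM; overrides \code{width}.
#' @return an \linkS4class{IRF}.
#' @examples
#' irf(center = 0, fwhm = "100fs")
#' @export
irf <- function(center = 0, width = NULL, fwhm = NULL) {
    if (!is.null(fwhm)) width <- asSeconds(fwhm) / (2 * sqrt(2 * log(2)))
    if (is.null(width)) stop("give width (sigma) or fwhm")
    new("IRF", center = asSeconds(center), width = asSeconds(width))
}

#' Construct a KineticBasis
#'
#' @param lifetimes lifetimes of the exponential components (seconds or unit
#'   strings); \code{Inf} denotes a persistent component (rate 0).
#' @param rates alternatively, rate constants in 1/s (0 = persistent).
#' @return a \linkS4class{KineticBasis}.
#' @examples
#' kineticBasis(lifetimes = c("848fs", "46ps", Inf))
#' @export
kineticBasis <- function(lifetimes = NULL, rates = NULL) {
    if (is.null(rates)) {
        if (is.null(lifetimes)) stop("give lifetimes or rates")
        if (is.character(lifetimes)) {
            inf <- lifetimes %in% c("Inf", "inf")
            tau <- rep(Inf, length(lifetimes))
            tau[!inf] <- asSeconds(lifetimes[!inf])
        } else tau <- as.numeric(lifetimes)
        rates <- ifelse(is.finite(tau), 1 / tau, 0)
    }
    new("KineticBasis", rates = as.numeric(rates))
}

#' Exponential decay convolved with a Gaussian IRF
#'
#' Closed-form convolution of \eqn{e^{-k(t-\mu)}\theta(t-\mu)} with a
#' Gaussian of width \eqn{\sigma}:
#' \deqn{c(t) = \tfrac12 e^{-k(t-\mu) + k^2\sigma^2/2}\,
#'   \mathrm{erfc}\!\left(\frac{\mu + k\sigma^2 - t}{\sigma\sqrt2}\right)}
#' evaluated in log space (via \code{pnorm(log.p = TRUE)}) so it stays
#' finite for \eqn{k\sigma} well beyond 10^3. For k = 0 it reduces to the
#' IRF-broadened step \eqn{\tfrac12\mathrm{erfc}((\mu-t)/\sigma\sqrt2)}.
#'
#' @param t times, seconds (numeric vector).
#' @param k rate constant, 1/s (k >= 0; 0 = persistent step).
#' @param irfObj an \linkS4class{IRF}.
#' @return amplitudes, same length as \code{t}.
#' @examples
#' convExp(c(0, 1e-12), k = 1e12, irf(0, fwhm = "100fs"))
#' @export
convExp <- function(t, k, irfObj) {
    validObject(irfObj)
    mu <- irfObj@center; sigma <- irfObj@width
    if (k < 0) stop("k must be >= 0")
    if (k == 0) return(stats::pnorm((t - mu) / sigma))
    # log of 0.5*erfc(b) with b = (mu + k sigma^2 - t)/(sigma sqrt 2)
    logHalfErfc <- stats::pnorm((t - mu - k * sigma^2) / sigma, log.p = TRUE)
    exp(0.5 * k^2 * sigma^2 - k * (t - mu) + logHalfErfc)
}

## Design matrix F: one IRF-convolved exponential per column.
.designMatrix <- function(times, basis, irfObj) {
    vapply(basis@rates, function(k) convExp(times, k, irfObj),
           numeric(length(times)))
}

#' Solve the linear least-squares step of the global fit
#'
#' Given fixed rate constants and IRF, finds the amplitude spectra B
#' minimizing \eqn{\chi^2 = \lVert \Delta A - F B \rVert^2}: the exact
#' linear projection of the data onto the IRF-convolved exponential basis.
#' Masked cells are excluded from the projection (per-wavelength solves
#' where the mask is row-dependent).
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param basis a \linkS4class{KineticBasis} (fixed rates).
#' @param irfObj an \linkS4class{IRF}.
#' @return list with \code{dads} (wavelengths x components), \code{chisq},
#'   \code{residuals} (wavelengths x times, NA on masked cells) and the
#'   design matrix \code{F}.
#' @export
solveDads <- function(m, basis, irfObj) {
    validObject(basis)
    F <- .designMatrix(m@times, basis, irfObj)
    nc <- ncol(F)
    if (nc > length(m@times))
        stop("more components than time points")
    qrF <- qr(F)
    if (qrF$rank < nc) {
        cc <- crossprod(F)
        d <- sqrt(diag(cc))
        corF <- cc / outer(d, d)
        worst <- which(abs(corF) == max(abs(corF[upper.tri(corF)])),
                       arr.ind = TRUE)[1, ]
        stop(sprintf(
            "rank-deficient exponential basis: components %d and %d are collinear (rates %.4g and %.4g 1/s)",
            worst[1], worst[2], basis@rates[worst[1]], basis@rates[worst[2]]))
    }
    Y <- t(m@values)                         # times x wavelengths
    anyMask <- any(m@mask)
    if (!anyMask) {
        B <- qr.coef(qrF, Y)                 # components x wavelengths
        R <- Y - F %*% B
    } else {
        B <- matrix(NA_real_, nc, ncol(Y))
        R <- matrix(NA_real_, nrow(Y), ncol(Y))
        for (j in seq_len(ncol(Y))) {
            keep <- !m@mask[j, ]
            if (sum(keep) < nc)
                stop("wavelength row ", j, " has fewer unmasked points than components")
            bj <- qr.coef(qr(F[keep, , drop = FALSE]), Y[keep, j])
            B[, j] <- bj
            R[keep, j] <- Y[keep, j] - F[keep, , drop = FALSE] %*% bj
        }
    }
    chisq <- sum(R^2, na.rm = TRUE)
    list(dads = t(B), chisq = chisq, residuals = t(R), F = F)
}

#' Variable-projection global fit of a TA matrix
#'
#' Fits \eqn{\Delta A(\lambda, t)} with a sum of exponentials convolved with
#' a Gaussian IRF. At every trial of the nonlinear parameters (log10 of the
#' decaying rate constants, optionally the IRF center) the amplitude
#' spectra are solved exactly by linear least squares
#' (\code{\link{solveDads}}); the nonlinear parameters are then optimized by
#' Levenberg-Marquardt on the projected residual. Components declared
#' persistent (lifetime Inf / rate 0) are kept as exact IRF-broadened steps
#' rather than tiny rates. Multistart with log-uniform jitter guards
#' against the multimodality of exponential fitting.
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param init a \linkS4class{KineticBasis} of initial rates (0 entries stay
#'   persistent and are not optimized), or lifetimes acceptable to
#'   \code{\link{kineticBasis}}.
#' @param irfInit an \linkS4class{IRF} initial guess.
#' @param floatIrfCenter optimize the IRF center mu (default TRUE; sigma
#'   stays fixed, as it is normally set by the coherent artefact).
#' @param multistarts number of starts; the first uses \code{init}
#'   unjittered, the rest jitter rates by a log-uniform factor in
#'   [0.2, 5].
#' @param seed RNG seed for the multistart jitter (reproducibility).
#' @param maxIter maximum Levenberg-Marquardt iterations per start.
#' @return a \linkS4class{DADSResult}; lowest chi-square start wins, ties
#'   break toward fewer iterations.
#' @examples
#' ## see the package vignette for a full worked example
#' @export
fitGlobal <- function(m, init, irfInit, floatIrfCenter = TRUE,
                      multistarts = 5, seed = 1, maxIter = 100) {
    if (!is(init, "KineticBasis")) init <- kineticBasis(lifetimes = init)
    validObject(init); validObject(irfInit)
    decaying <- init@rates > 0
    nDec <- sum(decaying)
    objective <- function(par) {
        k <- init@rates
        k[decaying] <- 10^par[seq_len(nDec)]
        mu <- if (floatIrfCenter) par[nDec + 1L] else irfInit@center
        b <- new("KineticBasis", rates = k)
        irfTrial <- new("IRF", center = mu, width = irfInit@width)
        sol <- solveDads(m, b, irfTrial)
        r <- sol$residuals
        r[is.na(r)] <- 0
        as.vector(r)
    }
    p0 <- log10(init@rates[decaying])
    if (floatIrfCenter) p0 <- c(p0, irfInit@center)
    set.seed(seed)
    starts <- vector("list", multistarts)
    starts[[1]] <- p0
    if (multistarts > 1) for (s in 2:multistarts) {
        p <- p0
        if (nDec > 0)
            p[seq_len(nDec)] <- p[seq_len(nDec)] +
                stats::runif(nDec, log10(0.2), log10(5))
        if (floatIrfCenter)
            p[nDec + 1L] <- p[nDec + 1L] +
                stats::rnorm(1, 0, irfInit@width / 2)
        starts[[s]] <- p
    }
    runs <- lapply(seq_len(multistarts), function(s) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = starts[[s]], fn = objective,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = maxIter, ptol = 1e-12,
                                   ftol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        list(par = fit$par, chisq = fit$deviance, iter = fit$niter,
             info = fit$info, start = s)
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs))
        stop("global fit failed to converge in every multistart")
    chis <- vapply(runs, `[[`, numeric(1), "chisq")
    iters <- vapply(runs, `[[`, numeric(1), "iter")
    best <- order(chis, iters)[1]
    par <- runs[[best]]$par
    k <- init@rates
    k[decaying] <- 10^par[seq_len(nDec)]
    muFit <- if (floatIrfCenter) par[nDec + 1L] else irfInit@center
    ## report components sorted fastest-first (persistent last)
    ord <- order(-k)
    basisFit <- new("KineticBasis", rates = k[ord])
    irfFit <- new("IRF", center = muFit, width = irfInit@width)
    sol <- solveDads(m, basisFit, irfFit)
    new("DADSResult", basis = basisFit, irf = irfFit, dads = sol$dads,
        wavelengths = m@wavelengths, times = m@times, chisq = sol$chisq,
        residuals = sol$residuals,
        convergence = list(
            bestStart = runs[[best]]$start, iterations = iters[best],
            perStart = data.frame(start = vapply(runs, `[[`, numeric(1), "start"),
                                  chisq = chis, iterations = iters)))
}

#' Sum of all DADS
#'
#' The component-wise sum of the decay-associated difference spectra, which
#' approximates the spectrum of the initially excited species minus the
#' ground state.
#'
#' @param r a \linkS4class{DADSResult}.
#' @return numeric spectrum on the result's wavelength grid.
#' @export
sumDads <- function(r) rowSums(r@dads)
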