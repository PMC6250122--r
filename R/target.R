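#' Construct a KineticModel
#'
#' @param compartments compartment names, in order.
#' @param K rate matrix in 1/s: K[i, j] is the transfer rate j -> i
#'   (off-diagonal, >= 0); diagonal entries are negative total loss rates.
#'   Any column deficit (|diagonal| exceeding the column's off-diagonal
#'   sum) is flux to the ground state.
#' @param p0 initial population vector; defaults to all population in the
#'   first compartment.
#' @return a \linkS4class{KineticModel}.
#' @examples
#' ## A -> B -> (ground), with 20% of A recombining directly to ground
#' sequentialModel(c("A", "B"), lifetimes = c("1ps", Inf),
#'                 branchToNext = c(0.8, 1))
#' @export
kineticModel <- function(compartments, K, p0 = NULL) {
    n <- length(compartments)
    if (is.null(p0)) p0 <- c(1, rep(0, n - 1))
    new("KineticModel", compartments = compartments, K = as.matrix(K),
        p0 = as.numeric(p0))
}

#' Sequential (optionally branched) kinetic scheme
#'
#' Convenience constructor for the chain A -> B -> C -> ..., where each
#' compartment decays with the given lifetime and a fraction
#' \code{branchToNext} of its decay flux feeds the next compartment (the
#' complement recombines to ground). The last compartment's decay, if
#' finite, goes entirely to ground.
#'
#' @param compartments names.
#' @param lifetimes per-compartment decay lifetimes (unit strings allowed,
#'   Inf = stable within the window).
#' @param branchToNext fraction of each decay feeding the next compartment.
#' @param p0 initial populations (default: first compartment).
#' @return a \linkS4class{KineticModel}.
#' @export
sequentialModel <- function(compartments, lifetimes,
                            branchToNext = rep(1, length(compartments)),
                            p0 = NULL) {
    n <- length(compartments)
    tau <- if (is.character(lifetimes)) {
        inf <- lifetimes %in% c("Inf", "inf")
        out <- rep(Inf, n); out[!inf] <- asSeconds(lifetimes[!inf]); out
    } else as.numeric(lifetimes)
    k <- ifelse(is.finite(tau), 1 / tau, 0)
    K <- matrix(0, n, n)
    diag(K) <- -k
    for (i in seq_len(n - 1))
        K[i + 1, i] <- k[i] * branchToNext[i]
    kineticModel(compartments, K, p0)
}

#' Compartment concentration profiles under IRF-shaped excitation
#'
#' Solves dC/dt = K C with the initial population p0 delivered through the
#' Gaussian IRF (impulsive excitation convolved with the instrument
#' response), by eigendecomposition of K: each kinetic eigenmode is an
#' IRF-convolved exponential (\code{\link{convExp}}), so the solution is
#' analytic on any time grid.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param irfObj an \linkS4class{IRF}.
#' @param times time grid, seconds (or unit strings).
#' @param ground also return the ground-state (lost flux) fraction column.
#' @return matrix, times x compartments (+ "ground" column if requested).
#' @export
concentrationProfiles <- function(model, irfObj, times, ground = FALSE) {
    validObject(model)
    times <- asSeconds(times)
    eg <- eigen(model@K)
    if (any(abs(Im(eg$values)) > 1e-9 * max(abs(eg$values), 1)))
        stop("complex eigenrates: scheme with reversible loops not supported")
    lam <- Re(eg$values)
    V <- Re(eg$vectors)
    if (abs(det(V)) < 1e-12)
        stop("defective rate matrix (repeated eigenrates); perturb the rates")
    w <- solve(V, model@p0)
    modes <- vapply(seq_along(lam), function(j) {
        k <- max(-lam[j], 0)
        convExp(times, k, irfObj)
    }, numeric(length(times)))
    C <- modes %*% t(V * rep(w, each = nrow(V)))
    C[C < 0 & C > -1e-12] <- 0
    colnames(C) <- model@compartments
    if (ground) {
        step <- convExp(times, 0, irfObj) * sum(model@p0)
        C <- cbind(C, ground = pmax(step - rowSums(C), 0))
    }
    C
}

## Amplitude map A with C(t) = F A, for model eigenrates matched to the
## fitted basis rates. Errors if the two rate sets disagree.
.amplitudeMap <- function(model, basis, matchTol = 1e-6) {
    eg <- eigen(model@K)
    lam <- Re(eg$values)
    V <- Re(eg$vectors)
    w <- solve(V, model@p0)
    kModel <- pmax(-lam, 0)
    kFit <- basis@rates
    if (length(kModel) != length(kFit))
        stop("model compartment count must equal the number of fitted components")
    assign <- integer(length(kFit))
    used <- logical(length(kModel))
    for (i in seq_along(kFit)) {
        rel <- abs(kModel - kFit[i]) / max(kFit[i], max(kModel), 1e-300)
        j <- which.min(replace(rel, used, Inf))
        if (rel[j] > matchTol)
            stop(sprintf(
                "model eigenrates do not match fitted rates (tol %.1g):\n  fitted: %s\n  model:  %s",
                matchTol, paste(signif(kFit, 6), collapse = ", "),
                paste(signif(sort(kModel, decreasing = TRUE), 6),
                      collapse = ", ")))
        assign[i] <- j
        used[j] <- TRUE
    }
    A <- matrix(0, length(kFit), nrow(V))
    for (i in seq_along(kFit))
        A[i, ] <- V[, assign[i]] * w[assign[i]]
    colnames(A) <- model@compartments
    A
}

#' Species-associated spectra from a DADS fit and a kinetic model
#'
#' Applies an explicit compartmental model to the model-free global-fit
#' result: the invertible linear map A between the exponential amplitudes
#' and the compartment concentrations (C = F A, from the eigenstructure of
#' K with the rates fixed to the fitted rates) turns the DADS into
#' species-associated spectra, SAS = (A^-1 B)'. The reconstruction F B is
#' untouched, so the chi-square of the fit is exactly preserved -- the model
#' changes the interpretation, not the quality of fit.
#'
#' @param r a \linkS4class{DADSResult}.
#' @param model a \linkS4class{KineticModel} whose eigenrates equal the
#'   fitted rates (within \code{matchTol}, relative).
#' @param matchTol relative eigenrate matching tolerance.
#' @return a \linkS4class{SASResult}.
#' @export
sasFromDads <- function(r, model, matchTol = 1e-6) {
    A <- .amplitudeMap(model, r@basis, matchTol)
    if (abs(det(A)) < 1e-300 * max(abs(A))^nrow(A) ||
        rcond(A) < 1e-12)
        stop("singular amplitude map: model unidentifiable from these rates")
    S <- t(solve(A, t(r@dads)))       # wavelengths x compartments
    colnames(S) <- model@compartments
    new("SASResult", sas = S, amplitudeMap = A, model = model,
        wavelengths = r@wavelengths, chisq = r@chisq)
}

#' Add a scaled ground-state spectrum to the DADS sum
#'
#' The DADS sum approximates (initially excited species - ground state)
#' times the excited fraction. Adding back the right amount of the
#' ground-state spectrum yields the pure excited-state spectrum and, with
#' it, the amount of ground state contributing to the data -- the
#' normalization needed for quantum-yield estimates. If \code{fraction} is
#' not given, the smallest fraction that removes the bleach (makes the
#' result nonnegative) inside \code{window} is used.
#'
#' @param sumSpec the DADS sum spectrum (see \code{\link{sumDads}}).
#' @param ground ground-state spectrum on the same grid.
#' @param wl wavelength grid, nm.
#' @param fraction ground-state fraction to add; NULL = estimate.
#' @param window bleach window in nm used for the estimate.
#' @return list with \code{spectrum} and \code{fraction}.
#' @export
addGroundState <- function(sumSpec, ground, wl, fraction = NULL,
                           window = c(430, 490)) {
    stopifnot(length(sumSpec) == length(wl), length(ground) == length(wl))
    if (is.null(fraction)) {
        inWin <- wl >= window[1] & wl <= window[2]
        g <- ground[inWin]; s <- sumSpec[inWin]
        ok <- g > 0.05 * max(g)
        if (!any(ok)) stop("ground spectrum vanishes in the bleach window")
        fraction <- max(0, max(-s[ok] / g[ok]))
    }
    list(spectrum = sumSpec + fraction * ground, fraction = fraction)
}

#' Strip the flavin difference spectrum from a DADS/SAS
#'
#' Subtracts alpha times the (radical minus oxidized) flavin difference
#' spectrum such that the flavin spectral features disappear from the
#' result. "Disappear" is operationalized as a least-squares projection of
#' the difference spectrum within a flavin-dominated window, with intercept
#' and linear-slope nuisance columns so that a flat or slowly varying
#' counter-radical background does not bias alpha; a decorrelation check on
#' the window residual is reported.
#'
#' @param spec input spectrum (e.g. the persistent DADS).
#' @param flavinDiff flavin difference spectrum (radical - oxidized) on the
#'   same grid, at unit population scale.
#' @param wl wavelength grid, nm.
#' @param window flavin-dominated window in nm. The default 445-500 nm sits
#'   red of the ~410 nm band of the tryptophanyl radical cation and blue of
#'   its broad 490-700 nm band, where the counter-radical background is
#'   smooth and the flavin difference spectrum carries its sharp vibronic
#'   structure.
#' @param baselineDegree polynomial degree of the nuisance baseline
#'   (0 = intercept only); the default cubic absorbs the smooth
#'   counter-radical tails.
#' @return list with \code{stripped} (full-grid spectrum), \code{alpha},
#'   and \code{windowCorrelation} between residual and difference spectrum.
#' @export
stripFlavin <- function(spec, flavinDiff, wl, window = c(445, 500),
                        baselineDegree = 3) {
    stopifnot(length(spec) == length(wl), length(flavinDiff) == length(wl))
    inWin <- wl >= window[1] & wl <= window[2]
    if (sum(inWin) < baselineDegree + 3L)
        stop("window contains too few grid points")
    d <- flavinDiff[inWin]
    if (stats::sd(d) < 1e-12 * max(abs(flavinDiff), 1e-300))
        stop("flavin difference spectrum is ~0 inside the window")
    Z <- cbind(flavin = d, intercept = 1)
    if (baselineDegree >= 1)
        Z <- cbind(Z, stats::poly(wl[inWin], degree = baselineDegree))
    cf <- qr.coef(qr(Z), spec[inWin])
    alpha <- unname(cf[1])
    resid <- spec[inWin] - Z %*% cf
    wcor <- if (stats::sd(resid) > 0) stats::cor(as.vector(resid), d) else 0
    list(stripped = spec - alpha * flavinDiff, alpha = alpha,
         windowCorrelation = wcor)
}

#' Radical-pair recombination fraction from the stripping coefficient
#'
#' If a fraction alpha of the flavin difference spectrum (at unit excited
#' population) is present in the persistent DADS, the complement 1 - alpha
#' of the primary radical pairs recombined to the ground state.
#'
#' @param alpha stripping coefficient from \code{\link{stripFlavin}};
#'   must lie in [0, 1.2] (tolerant of noise overshoot).
#' @return recombination fraction in [0, 1].
#' @examples
#' estimateRpr(0.8)  # 0.2
#' @export
estimateRpr <- function(alpha) {
    if (!is.finite(alpha) || alpha < 0 || alpha > 1.2)
        stop("alpha outside the admissible range [0, 1.2]: ", alpha)
    min(max(1 - alpha, 0), 1)
}
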