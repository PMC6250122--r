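#' @import methods
NULL

.POLARIZATIONS <- c("magic", "parallel", "perpendicular", "unpolarized")

#' TAMatrix: a time-resolved difference-absorption matrix
#'
#' Container for a transient-absorption surface \eqn{\Delta A(\lambda, t)}:
#' rows are wavelengths (nm, ascending), columns are delay times (seconds,
#' ascending; constructors accept unit-suffixed input). Cells excluded from
#' analysis (scatter, emission, out-of-range after chirp correction) are
#' flagged in \code{mask}; masked cells never enter a fit.
#'
#' @slot wavelengths numeric, strictly ascending probe wavelengths in nm.
#' @slot times numeric, strictly ascending delay times in seconds.
#' @slot values numeric matrix of \eqn{\Delta A} in OD,
#'   \code{length(wavelengths)} x \code{length(times)}.
#' @slot polarization one of \code{"magic"}, \code{"parallel"},
#'   \code{"perpendicular"}, \code{"unpolarized"}.
#' @slot mask logical matrix, same shape as \code{values}; \code{TRUE} marks
#'   excluded cells.
#' @slot meta free-form provenance list.
#' @export
setClass("TAMatrix",
    representation(
        wavelengths  = "numeric",
        times        = "numeric",
        values       = "matrix",
        polarization = "character",
        mask         = "matrix",
        meta         = "list"
    ),
    prototype(polarization = "magic", meta = list())
)

setValidity("TAMatrix", function(object) {
    msgs <- character()
    if (length(object@wavelengths) < 1L || any(diff(object@wavelengths) <= 0))
        msgs <- c(msgs, "wavelengths must be strictly ascending")
    if (length(object@times) < 1L || any(diff(object@times) <= 0))
        msgs <- c(msgs, "times must be strictly ascending")
    if (!identical(dim(object@values),
                   c(length(object@wavelengths), length(object@times))))
        msgs <- c(msgs, "values must be length(wavelengths) x length(times)")
    if (!identical(dim(object@mask), dim(object@values)))
        msgs <- c(msgs, "mask must have the same shape as values")
    if (!is.logical(object@mask))
        msgs <- c(msgs, "mask must be logical")
    if (length(object@polarization) != 1L ||
        !object@polarization %in% .POLARIZATIONS)
        msgs <- c(msgs, sprintf("polarization must be one of %s",
                                paste(.POLARIZATIONS, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' StreakTriplet: raw streak-camera image triple
#'
#' The three shutter-sequenced images from which a transient-absorption
#' surface is computed: \code{dFL} (flash lamp + laser), \code{d0} (no light),
#' \code{dF} (flash lamp only), on a common wavelength x time grid.
#'
#' @slot wavelengths,times common grids (nm, seconds).
#' @slot dFL,d0,dF nonnegative intensity matrices of identical shape.
#' @slot nSequences number of averaged acquisition sequences.
#' @export
setClass("StreakTriplet",
    representation(
        wavelengths = "numeric",
        times       = "numeric",
        dFL         = "matrix",
        d0          = "matrix",
        dF          = "matrix",
        nSequences  = "numeric"
    ),
    prototype(nSequences = 1)
)

setValidity("StreakTriplet", function(object) {
    msgs <- character()
    dd <- c(length(object@wavelengths), length(object@times))
    for (nm in c("dFL", "d0", "dF")) {
        m <- slot(object, nm)
        if (!identical(dim(m), dd))
            msgs <- c(msgs, sprintf("%s must match the axis grids", nm))
        if (any(m < 0, na.rm = TRUE))
            msgs <- c(msgs, sprintf("%s must be nonnegative", nm))
    }
    if (object@nSequences < 1)
        msgs <- c(msgs, "nSequences must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' ChirpModel: polynomial group-delay model of the white-light probe
#'
#' Time zero as a function of wavelength, \eqn{t_0(\lambda) = \sum_j c_j
#' (\lambda - \lambda_0)^j}, in seconds per nm^j. Used to dechirp
#' femtosecond data: the coherent artefact marks \eqn{t_0} at each wavelength.
#'
#' @slot coefficients polynomial coefficients, ascending order, seconds/nm^j.
#' @slot lambda0 reference wavelength in nm.
#' @slot window maximal admissible |t0| spread in seconds (validity guard;
#'   a supercontinuum chirp is of order 1.5 ps).
#' @export
setClass("ChirpModel",
    representation(coefficients = "numeric", lambda0 = "numeric",
                   window = "numeric"),
    prototype(coefficients = 0, lambda0 = 500, window = 20e-12)
)

setValidity("ChirpModel", function(object) {
    if (length(object@coefficients) < 1L) return("need >= 1 coefficient")
    if (object@window <= 0) return("window must be > 0")
    TRUE
})

#' IRF: Gaussian instrument response function
#'
#' @slot center temporal center \eqn{\mu} in seconds.
#' @slot width Gaussian standard deviation \eqn{\sigma} in seconds
#'   (FWHM = \eqn{2\sqrt{2\ln 2}\,\sigma}).
#' @export
setClass("IRF",
    representation(center = "numeric", width = "numeric"),
    prototype(center = 0, width = 1e-13)
)

setValidity("IRF", function(object) {
    if (length(object@width) != 1L || !is.finite(object@width) ||
        object@width <= 0) return("width (sigma) must be a positive scalar")
    if (length(object@center) != 1L || !is.finite(object@center))
        return("center must be a finite scalar")
    TRUE
})

#' KineticBasis: rate constants of the exponential fit basis
#'
#' Each rate k_i (1/s) defines one IRF-convolved exponential decay; k = 0
#' encodes a persistent component (a species that does not decay within the
#' observation window), realized as an IRF-broadened step.
#'
#' @slot rates numeric, nonnegative, pairwise distinct rate constants in 1/s.
#' @export
setClass("KineticBasis", representation(rates = "numeric"))

setValidity("KineticBasis", function(object) {
    k <- object@rates
    if (length(k) < 1L) return("need >= 1 rate")
    if (any(!is.finite(k)) || any(k < 0)) return("rates must be finite and >= 0")
    if (length(k) > 1L) {
        for (i in seq_len(length(k) - 1L)) for (j in (i + 1L):length(k)) {
            s <- max(k[i], k[j])
            if (s == 0 || abs(k[i] - k[j]) / s <= 1e-9)
                return(sprintf("rates %d and %d are not distinct", i, j))
        }
    }
    TRUE
})

#' DADSResult: outcome of a variable-projection global fit
#'
#' @slot basis optimized \linkS4class{KineticBasis}.
#' @slot irf optimized \linkS4class{IRF}.
#' @slot dads decay-associated difference spectra, wavelengths x components,
#'   OD.
#' @slot wavelengths probe grid in nm.
#' @slot times delay grid in seconds.
#' @slot chisq sum of squared residuals at the reported parameters.
#' @slot residuals residual matrix (wavelengths x times; NA on masked cells).
#' @slot convergence diagnostics list (iterations, multistart table, ...).
#' @export
setClass("DADSResult",
    representation(
        basis       = "KineticBasis",
        irf         = "IRF",
        dads        = "matrix",
        wavelengths = "numeric",
        times       = "numeric",
        chisq       = "numeric",
        residuals   = "matrix",
        convergence = "list"
    )
)

setValidity("DADSResult", function(object) {
    if (ncol(object@dads) != length(object@basis@rates))
        return("one DADS column per rate constant required")
    if (nrow(object@dads) != length(object@wavelengths))
        return("DADS rows must match the wavelength grid")
    TRUE
})

#' RankReport: SVD-based rank analysis of a TA matrix
#'
#' @slot singularValues descending singular values.
#' @slot autocorrLeft,autocorrRight first-lag autocorrelations of the left
#'   (spectral) and right (temporal) singular vectors.
#' @slot rank recommended number of kinetic components.
#' @slot noiseFloor singular-value noise-floor estimate.
#' @slot autocorrThreshold threshold used for the vector criterion.
#' @export
setClass("RankReport",
    representation(
        singularValues    = "numeric",
        autocorrLeft      = "numeric",
        autocorrRight     = "numeric",
        rank              = "integer",
        noiseFloor        = "numeric",
        autocorrThreshold = "numeric"
    )
)

setValidity("RankReport", function(object) {
    sv <- object@singularValues
    if (any(sv < 0) || is.unsorted(rev(sort(sv))) && any(diff(sv) > 0))
        return("singular values must be nonnegative and descending")
    if (object@rank < 0L || object@rank > length(sv))
        return("rank must lie in [0, length(singularValues)]")
    TRUE
})

#' KineticModel: first-order compartment scheme
#'
#' dC/dt = K C with off-diagonal K[i, j] >= 0 the transfer rate from
#' compartment j to i and column sums <= 0; the deficit of a column is flux
#' to the ground state (loss channel). p0 is the initial (photo-generated)
#' population entering through the instrument response.
#'
#' @slot compartments compartment names.
#' @slot K rate matrix, 1/s.
#' @slot p0 initial population vector (entries in [0, 1], sum 1).
#' @export
setClass("KineticModel",
    representation(compartments = "character", K = "matrix", p0 = "numeric")
)

setValidity("KineticModel", function(object) {
    n <- length(object@compartments)
    msgs <- character()
    if (!identical(dim(object@K), c(n, n)))
        msgs <- c(msgs, "K must be n x n for n compartments")
    off <- object@K; diag(off) <- 0
    if (any(off < 0)) msgs <- c(msgs, "off-diagonal rates must be >= 0")
    if (any(colSums(object@K) > 1e-9 * max(abs(object@K), 1)))
        msgs <- c(msgs, "column sums of K must be <= 0 (flux conservation)")
    if (length(object@p0) != n || any(object@p0 < 0) || any(object@p0 > 1) ||
        abs(sum(object@p0) - 1) > 1e-9)
        msgs <- c(msgs, "p0 entries must lie in [0,1] and sum to 1")
    if (length(msgs)) msgs else TRUE
})

#' SASResult: species-associated spectra from target analysis
#'
#' @slot sas species-associated spectra, wavelengths x compartments, OD.
#' @slot amplitudeMap matrix A with C(t) = F A: links the exponential basis
#'   to compartment concentrations.
#' @slot model the applied \linkS4class{KineticModel}.
#' @slot wavelengths probe grid, nm.
#' @slot chisq chi-square, identical to the DADS fit's by construction.
#' @export
setClass("SASResult",
    representation(
        sas          = "matrix",
        amplitudeMap = "matrix",
        model        = "KineticModel",
        wavelengths  = "numeric",
        chisq        = "numeric"
    )
)

#' BasisSet: named species spectra on one wavelength grid
#'
#' @slot wavelengths grid in nm, ascending.
#' @slot spectra matrix, wavelengths x species; colnames are species names.
#' @export
setClass("BasisSet",
    representation(wavelengths = "numeric", spectra = "matrix")
)

setValidity("BasisSet", function(object) {
    msgs <- character()
    if (any(diff(object@wavelengths) <= 0))
        msgs <- c(msgs, "wavelengths must be strictly ascending")
    if (nrow(object@spectra) != length(object@wavelengths))
        msgs <- c(msgs, "spectra rows must match the wavelength grid")
    if (ncol(object@spectra) < 1L)
        msgs <- c(msgs, "need >= 1 species")
    if (is.null(colnames(object@spectra)))
        msgs <- c(msgs, "spectra columns must be named")
    if (length(msgs)) msgs else TRUE
})

#' MoleFractionProfile: decomposition of data over species basis spectra
#'
#' @slot index time points (seconds) or pulse indices of the decomposed
#'   spectra.
#' @slot fractions matrix, time points x species.
#' @slot residualNorm per-point residual 2-norm of the least-squares fit.
#' @slot sumDeviation per-point deviation of the species sum from 1
#'   (monitored, never silently renormalized).
#' @export
setClass("MoleFractionProfile",
    representation(
        index        = "numeric",
        fractions    = "matrix",
        residualNorm = "numeric",
        sumDeviation = "numeric"
    )
)

setValidity("MoleFractionProfile", function(object) {
    n <- length(object@index)
    if (nrow(object@fractions) != n ||
        length(object@residualNorm) != n || length(object@sumDeviation) != n)
        return("per-point slots must share one length")
    TRUE
})

#' PhotocycleParams: rates, branchings and yields of the photocycle scheme
#'
#' All times in seconds. The scheme: photoexcitation, sub-ps electron
#' transfer along the Trp tetrad to FAD (tauET1), decay of the primary
#' radical pair (tauET2) branching between recombination (phiRec, to ground)
#' and onward transfer, formation of the terminal radical pair in the ns gap
#' (tauRP4), its deprotonation (tauDeprot), decay/decomposition of the
#' neutral Trp radical (tauTrpDecay), and O2-dependent reoxidation of the
#' flavin anion radical (kReox x o2, pseudo-first-order 1/s).
#'
#' @slot tauET1 primary electron-transfer lifetime, s.
#' @slot tauET2 primary radical-pair decay lifetime, s.
#' @slot phiRec radical-pair recombination branching fraction in [0, 1].
#' @slot tauRP4 terminal-radical-pair formation lifetime, s (bounded
#'   between the ps window end and ~100 ns).
#' @slot tauDeprot TrpH radical-cation deprotonation lifetime, s.
#' @slot tauTrpDecay neutral Trp radical decay lifetime, s.
#' @slot kReox FAD anion reoxidation rate at unit relative O2, 1/s.
#' @slot phiRelease per-photon free-FAD release probability of a protein
#'   whose sacrificial Trp positions are all decomposed.
#' @slot nTrpSacrificial number of sacrificial Trp tetrad positions.
#' @slot pocketPKa pKa of the flavin radical protonation equilibrium.
#' @slot pocketPH local pH of the FAD binding pocket.
#' @slot excPerSecond mean excitations per flavin per second of illumination.
#' @export
setClass("PhotocycleParams",
    representation(
        tauET1          = "numeric",
        tauET2          = "numeric",
        phiRec          = "numeric",
        tauRP4          = "numeric",
        tauDeprot       = "numeric",
        tauTrpDecay     = "numeric",
        kReox           = "numeric",
        phiRelease      = "numeric",
        nTrpSacrificial = "numeric",
        pocketPKa       = "numeric",
        pocketPH        = "numeric",
        excPerSecond    = "numeric"
    )
)

setValidity("PhotocycleParams", function(object) {
    msgs <- character()
    taus <- c(object@tauET1, object@tauET2, object@tauRP4, object@tauDeprot,
              object@tauTrpDecay)
    if (any(!is.finite(taus)) || any(taus <= 0))
        msgs <- c(msgs, "all lifetimes must be finite and > 0")
    for (nm in c("phiRec", "phiRelease")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) msgs <- c(msgs, sprintf("%s must be in [0,1]", nm))
    }
    if (object@kReox < 0) msgs <- c(msgs, "kReox must be >= 0")
    if (object@nTrpSacrificial < 0 ||
        object@nTrpSacrificial != round(object@nTrpSacrificial))
        msgs <- c(msgs, "nTrpSacrificial must be a nonnegative integer")
    if (object@tauRP4 <= object@tauET2)
        msgs <- c(msgs, "tauRP4 must exceed the ps-regime lifetimes")
    if (object@excPerSecond < 0)
        msgs <- c(msgs, "excPerSecond must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' IlluminationSchedule: ordered blue-light pulse sequence
#'
#' @slot durations pulse durations in seconds.
#' @slot energies pulse energies in mJ (informational; dose scales with
#'   duration via PhotocycleParams@excPerSecond).
#' @slot darkIntervals dark incubation gaps between pulses in seconds (full
#'   reoxidation is assumed between pulses).
#' @export
setClass("IlluminationSchedule",
    representation(durations = "numeric", energies = "numeric",
                   darkIntervals = "numeric")
)

setValidity("IlluminationSchedule", function(object) {
    msgs <- character()
    if (length(object@durations) < 1L || any(object@durations <= 0))
        msgs <- c(msgs, "durations must be positive")
    if (length(object@energies) != length(object@durations))
        msgs <- c(msgs, "energies must match durations in length")
    if (length(object@darkIntervals) != length(object@durations))
        msgs <- c(msgs, "darkIntervals must match durations in length")
    if (length(msgs)) msgs else TRUE
})
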