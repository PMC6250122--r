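#' @include AllClasses.R
NULL

#' Accessors for spectro-temporal containers
#'
#' Standard read accessors for the classes in this package; slot access in
#' user code should go through these.
#'
#' @param object an object of the documented classes.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("taValues", function(object) standardGeneric("taValues"))
#' @rdname accessors
#' @export
setGeneric("taMask", function(object) standardGeneric("taMask"))
#' @rdname accessors
#' @export
setGeneric("polarization", function(object) standardGeneric("polarization"))
#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))
#' @rdname accessors
#' @export
setGeneric("dads", function(object) standardGeneric("dads"))
#' @rdname accessors
#' @export
setGeneric("sas", function(object) standardGeneric("sas"))
#' @rdname accessors
#' @export
setGeneric("chisq", function(object) standardGeneric("chisq"))
#' @rdname accessors
#' @export
setGeneric("moleFractions", function(object) standardGeneric("moleFractions"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("recommendedRank", function(object) standardGeneric("recommendedRank"))

setMethod("wavelengths", "TAMatrix", function(object) object@wavelengths)
setMethod("wavelengths", "DADSResult", function(object) object@wavelengths)
setMethod("wavelengths", "SASResult", function(object) object@wavelengths)
setMethod("wavelengths", "BasisSet", function(object) object@wavelengths)
setMethod("wavelengths", "StreakTriplet", function(object) object@wavelengths)

setMethod("timePoints", "TAMatrix", function(object) object@times)
setMethod("timePoints", "DADSResult", function(object) object@times)
setMethod("timePoints", "StreakTriplet", function(object) object@times)

setMethod("taValues", "TAMatrix", function(object) object@values)
setMethod("taMask", "TAMatrix", function(object) object@mask)
setMethod("polarization", "TAMatrix", function(object) object@polarization)

setMethod("rates", "KineticBasis", function(object) object@rates)
setMethod("rates", "DADSResult", function(object) object@basis@rates)
setMethod("rates", "KineticModel", function(object) object@K)

setMethod("lifetimes", "KineticBasis", function(object) {
    k <- object@rates
    ifelse(k > 0, 1 / k, Inf)
})
setMethod("lifetimes", "DADSResult",
          function(object) lifetimes(object@basis))

setMethod("dads", "DADSResult", function(object) object@dads)
setMethod("sas", "SASResult", function(object) object@sas)
setMethod("chisq", "DADSResult", function(object) object@chisq)
setMethod("chisq", "SASResult", function(object) object@chisq)

setMethod("moleFractions", "MoleFractionProfile",
          function(object) object@fractions)
setMethod("speciesNames", "BasisSet",
          function(object) colnames(object@spectra))
setMethod("speciesNames", "KineticModel", function(object) object@compartments)
setMethod("speciesNames", "MoleFractionProfile",
          function(object) colnames(object@fractions))
setMethod("recommendedRank", "RankReport", function(object) object@rank)

setMethod("show", "TAMatrix", function(object) {
    tr <- range(object@times)
    cat(sprintf("TAMatrix: %d wavelengths x %d times (%s polarization)\n",
                length(object@wavelengths), length(object@times),
                object@polarization))
    cat(sprintf("  lambda: %.1f..%.1f nm | t: %s..%s | masked cells: %d\n",
                min(object@wavelengths), max(object@wavelengths),
                formatTime(tr[1]), formatTime(tr[2]), sum(object@mask)))
})

setMethod("show", "DADSResult", function(object) {
    tau <- lifetimes(object)
    cat(sprintf("DADSResult: %d components, chi^2 = %.4g\n",
                length(tau), object@chisq))
    cat("  lifetimes:", paste(vapply(tau, formatTime, ""), collapse = ", "),
        "\n")
})

setMethod("show", "RankReport", function(object) {
    cat(sprintf("RankReport: recommended rank %d (noise floor %.3g)\n",
                object@rank, object@noiseFloor))
    n <- min(6L, length(object@singularValues))
    tab <- data.frame(
        sv = signif(object@singularValues[seq_len(n)], 4),
        acLeft = round(object@autocorrLeft[seq_len(n)], 3),
        acRight = round(object@autocorrRight[seq_len(n)], 3))
    print(tab)
})

setMethod("show", "SASResult", function(object) {
    cat(sprintf("SASResult: %d compartments (%s), chi^2 = %.4g\n",
                ncol(object@sas),
                paste(object@model@compartments, collapse = " > "),
                object@chisq))
})

setMethod("show", "BasisSet", function(object) {
    cat(sprintf("BasisSet: %d species on %d-point grid (%.0f..%.0f nm)\n",
                ncol(object@spectra), length(object@wavelengths),
                min(object@wavelengths), max(object@wavelengths)))
    cat("  species:", paste(colnames(object@spectra), collapse = ", "), "\n")
})

setMethod("show", "MoleFractionProfile", function(object) {
    cat(sprintf("MoleFractionProfile: %d points x %d species\n",
                length(object@index), ncol(object@fractions)))
    cat(sprintf("  max |sum - 1| = %.3g, max residual norm = %.3g\n",
                max(abs(object@sumDeviation)), max(object@residualNorm)))
})

setMethod("show", "PhotocycleParams", function(object) {
    cat("PhotocycleParams:\n")
    cat(sprintf("  tauET1 %s | tauET2 %s | phiRec %.2f | tauRP4 %s\n",
                formatTime(object@tauET1), formatTime(object@tauET2),
                object@phiRec, formatTime(object@tauRP4)))
    cat(sprintf("  tauDeprot %s | tauTrpDecay %s | kReox %.3g 1/s\n",
                formatTime(object@tauDeprot), formatTime(object@tauTrpDecay),
                object@kReox))
    cat(sprintf("  phiRelease %.3f | nTrpSacrificial %d | pocket pH %.1f (pKa %.1f)\n",
                object@phiRelease, as.integer(object@nTrpSacrificial),
                object@pocketPH, object@pocketPKa))
})
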