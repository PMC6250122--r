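#' Construct a TAMatrix
#'
#' @param wavelengths ascending probe wavelengths, nm.
#' @param times ascending delay times; numeric seconds or unit-suffixed
#'   strings (see \code{\link{asSeconds}}).
#' @param values \eqn{\Delta A} matrix (OD), wavelengths x times.
#' @param polarization one of "magic", "parallel", "perpendicular",
#'   "unpolarized".
#' @param mask optional logical matrix, TRUE = excluded cell.
#' @param meta provenance list.
#' @return a \linkS4class{TAMatrix}.
#' @examples
#' m <- taMatrix(400:410, c("0ps", "1ps", "10ps"), matrix(0, 11, 3))
#' @export
taMatrix <- function(wavelengths, times, values, polarization = "magic",
                     mask = NULL, meta = list()) {
    times <- asSeconds(times)
    values <- as.matrix(values)
    if (is.null(mask))
        mask <- matrix(FALSE, nrow(values), ncol(values))
    mask <- mask | !is.finite(values)
    new("TAMatrix", wavelengths = as.numeric(wavelengths), times = times,
        values = values, polarization = polarization, mask = mask,
        meta = meta)
}

#' Construct a StreakTriplet
#'
#' @param wavelengths,times common grids (nm; seconds or unit strings).
#' @param dFL image with flash lamp and laser.
#' @param d0 dark image (no incoming light).
#' @param dF image with flash lamp only.
#' @param nSequences number of averaged acquisitions.
#' @return a \linkS4class{StreakTriplet}.
#' @export
streakTriplet <- function(wavelengths, times, dFL, d0, dF, nSequences = 1) {
    new("StreakTriplet", wavelengths = as.numeric(wavelengths),
        times = asSeconds(times), dFL = as.matrix(dFL), d0 = as.matrix(d0),
        dF = as.matrix(dF), nSequences = nSequences)
}

#' Construct a ChirpModel
#'
#' @param coefficients polynomial coefficients of t0(lambda), ascending
#'   powers of (lambda - lambda0); seconds per nm^j (strings allowed for the
#'   constant term).
#' @param lambda0 reference wavelength, nm.
#' @param window admissible |t0| spread guard, seconds.
#' @return a \linkS4class{ChirpModel}.
#' @export
chirpModel <- function(coefficients, lambda0 = 500, window = "20ps") {
    new("ChirpModel", coefficients = as.numeric(coefficients),
        lambda0 = lambda0, window = asSeconds(window))
}

#' Evaluate a chirp model: time zero per wavelength
#' @param c a \linkS4class{ChirpModel}.
#' @param lambda wavelengths, nm.
#' @return t0(lambda) in seconds.
#' @export
evalChirp <- function(c, lambda) {
    x <- lambda - c@lambda0
    t0 <- rep(0, length(lambda))
    for (j in seq_along(c@coefficients))
        t0 <- t0 + c@coefficients[j] * x^(j - 1)
    spread <- diff(range(t0))
    if (spread > c@window)
        stop(sprintf("chirp spread %.3g s exceeds the admissible window %.3g s",
                     spread, c@window))
    t0
}

#' Transient absorption from a streak-camera image triplet
#'
#' Computes the decadic difference absorption
#' \deqn{\Delta A = -\log_{10}\frac{D_{FL} - D_0}{D_F - D_0}}
#' from the three shutter-sequenced images. Cells where either numerator or
#' denominator is nonpositive carry no photometric information and are
#' masked, never fabricated.
#'
#' @param triplet a \linkS4class{StreakTriplet}.
#' @param polarization polarization tag for the result.
#' @return a \linkS4class{TAMatrix} in OD.
#' @export
taFromStreak <- function(triplet, polarization = "magic") {
    validObject(triplet)
    num <- triplet@dFL - triplet@d0
    den <- triplet@dF - triplet@d0
    bad <- num <= 0 | den <= 0
    vals <- matrix(NA_real_, nrow(num), ncol(num))
    vals[!bad] <- -log10(num[!bad] / den[!bad])
    if (all(bad))
        warning("all cells masked: no usable probe intensity anywhere")
    taMatrix(triplet@wavelengths, triplet@times, vals,
             polarization = polarization, mask = bad,
             meta = list(source = "streak", nSequences = triplet@nSequences))
}

#' Subtract the averaged pre-time-zero scatter signal
#'
#' For each wavelength, the mean over all columns with t <= tMaxPre (pump
#' scatter reaching the detector before the pump-probe overlap) is
#' subtracted from the full row. Idempotent: a second application changes
#' nothing.
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param tMaxPre latest time included in the pre-t0 average (seconds or
#'   unit string).
#' @param minPoints minimum number of pre-t0 columns required.
#' @return the corrected \linkS4class{TAMatrix}.
#' @export
subtractPreT0 <- function(m, tMaxPre, minPoints = 3L) {
    tMaxPre <- asSeconds(tMaxPre)
    pre <- which(m@times <= tMaxPre)
    if (length(pre) < minPoints)
        stop(sprintf("need >= %d pre-t0 time points, found %d",
                     minPoints, length(pre)))
    vals <- m@values
    vals[m@mask] <- NA
    offset <- rowMeans(vals[, pre, drop = FALSE], na.rm = TRUE)
    offset[!is.finite(offset)] <- 0
    out <- m
    out@values <- m@values - offset
    out@meta$preT0Subtracted <- tMaxPre
    out
}

#' Correct the white-light chirp
#'
#' Each wavelength row is shifted in time by -t0(lambda) via piecewise-cubic
#' interpolation onto the common delay axis, so the coherent artefact (and
#' with it time zero) aligns across the probe spectrum. Points that would
#' come from outside the measured axis are masked.
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param chirp a \linkS4class{ChirpModel}.
#' @return the dechirped \linkS4class{TAMatrix}.
#' @export
chirpCorrect <- function(m, chirp) {
    t0 <- evalChirp(chirp, m@wavelengths)
    if (all(t0 == 0)) return(m)
    out <- m
    tr <- range(m@times)
    for (i in seq_along(m@wavelengths)) {
        if (t0[i] == 0) next
        src <- m@times + t0[i]          # value at shifted position
        outside <- src < tr[1] | src > tr[2]
        keep <- !m@mask[i, ]
        if (sum(keep) < 4L) { out@mask[i, ] <- TRUE; next }
        f <- stats::splinefun(m@times[keep], m@values[i, keep], method = "fmm")
        v <- f(src)
        v[outside] <- NA
        out@values[i, ] <- v
        out@mask[i, ] <- m@mask[i, ] | outside
    }
    if (any(out@mask & !m@mask))
        out@meta$chirpMaskedCells <- sum(out@mask & !m@mask)
    out@meta$chirpCorrected <- TRUE
    out
}

#' Quasi-logarithmic delay-time axis
#'
#' Linear spacing from tMin to tSwitch, then logarithmic up to tMax with
#' equal point counts per decade, so dynamics on every timescale carry equal
#' weight in a uniform least-squares fit. The linear segment receives the
#' same number of points as one decade of the logarithmic segment.
#'
#' @param tMin,tSwitch,tMax axis limits (seconds or unit strings);
#'   tMin < tSwitch < tMax, tSwitch > 0.
#' @param nPoints total number of points (>= 10 for a usable axis; smaller
#'   values are honoured for degenerate axes).
#' @return strictly increasing numeric vector of length nPoints.
#' @examples
#' t <- buildTimeAxis("-1ps", "1ps", "3ns", 500)
#' @export
buildTimeAxis <- function(tMin, tSwitch, tMax, nPoints) {
    tMin <- asSeconds(tMin); tSwitch <- asSeconds(tSwitch)
    tMax <- asSeconds(tMax)
    if (!(tMin < tSwitch && tSwitch < tMax))
        stop("need tMin < tSwitch < tMax")
    if (tSwitch <= 0) stop("tSwitch must be positive for the log segment")
    nPoints <- as.integer(nPoints)
    if (nPoints < 3L) stop("need at least 3 points")
    nDecades <- log10(tMax / tSwitch)
    # one "decade equivalent" for the linear segment
    nLin <- max(2L, round(nPoints / (1 + nDecades)))
    nLog <- nPoints - nLin + 1L          # shares tSwitch
    if (nLog < 2L) { nLog <- 2L; nLin <- nPoints - 1L }
    lin <- seq(tMin, tSwitch, length.out = nLin)
    lg <- 10^seq(log10(tSwitch), log10(tMax), length.out = nLog)
    out <- c(lin, lg[-1])
    stopifnot(length(out) == nPoints, all(diff(out) > 0))
    out
}

#' Write / read a TA matrix as delimited text
#'
#' Dialect: first row holds the delay times (seconds), first column the
#' wavelengths (nm), the top-left cell is empty; masked cells are written as
#' NA and restored into the mask on reading.
#'
#' @param m a \linkS4class{TAMatrix}.
#' @param file path.
#' @param sep field separator.
#' @return \code{writeTAMatrix}: the path, invisibly. \code{readTAMatrix}:
#'   a \linkS4class{TAMatrix}.
#' @export
writeTAMatrix <- function(m, file, sep = ",") {
    vals <- m@values
    vals[m@mask] <- NA
    header <- paste(c("", sprintf("%.17g", m@times)), collapse = sep)
    body <- apply(cbind(sprintf("%.17g", m@wavelengths),
                        matrix(sprintf("%.17g", vals), nrow(vals))),
                  1, paste, collapse = sep)
    writeLines(c(header, body), file)
    invisible(file)
}

#' @rdname writeTAMatrix
#' @param polarization polarization tag to attach on reading.
#' @export
readTAMatrix <- function(file, sep = ",", polarization = "magic") {
    raw <- utils::read.table(file, sep = sep, header = FALSE,
                             stringsAsFactors = FALSE)
    times <- as.numeric(raw[1, -1])
    wl <- as.numeric(raw[-1, 1])
    vals <- as.matrix(raw[-1, -1])
    storage.mode(vals) <- "double"
    dimnames(vals) <- NULL
    taMatrix(wl, times, vals, polarization = polarization,
             mask = !is.finite(vals))
}
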