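## Time-unit helpers. All internal times are seconds; user-facing
## constructors accept unit-suffixed strings ("848fs", "46ps", "187ms").

.TIME_UNITS <- c(fs = 1e-15, ps = 1e-12, ns = 1e-9, us = 1e-6,
                 "μs" = 1e-6, ms = 1e-3, s = 1, min = 60)

#' Parse a time quantity with unit suffix into seconds
#'
#' Accepts numerics (taken as seconds) or strings such as \code{"848fs"},
#' \code{"46 ps"}, \code{"1us"}, \code{"187ms"}, \code{"3min"}.
#'
#' @param x numeric or character vector.
#' @return numeric vector of times in seconds.
#' @examples
#' asSeconds(c("848fs", "46ps", "187ms"))
#' @export
asSeconds <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(as.character(x), function(s) {
        s <- gsub(" ", "", s)
        m <- regmatches(s, regexec("^([-+0-9.eE]+)([a-zμ]*)$", s))[[1]]
        if (length(m) != 3L) stop("cannot parse time quantity: ", s)
        val <- as.numeric(m[2])
        unit <- if (nzchar(m[3])) m[3] else "s"
        if (!unit %in% names(.TIME_UNITS))
            stop("unknown time unit '", unit, "' in: ", s)
        val * .TIME_UNITS[[unit]]
    }, numeric(1), USE.NAMES = FALSE)
}

#' Format a time in seconds with a readable unit
#' @param t scalar time in seconds.
#' @return character scalar, e.g. "848 fs".
#' @export
formatTime <- function(t) {
    if (!is.finite(t)) return("inf")
    if (t == 0) return("0 s")
    a <- abs(t)
    units <- c(fs = 1e-15, ps = 1e-12, ns = 1e-9, us = 1e-6, ms = 1e-3, s = 1)
    i <- max(which(a >= units * 0.9995), 1L)
    sprintf("%.3g %s", t / units[i], names(units)[i])
}

## Gaussian band in wavelength, parameterized by center/FWHM/amplitude.
.gaussBand <- function(lambda, center, fwhm, amplitude) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    amplitude * exp(-0.5 * ((lambda - center) / sigma)^2)
}

## First-lag autocorrelation of a vector (population definition, as used to
## separate smooth singular vectors from noise-like ones).
.lag1Autocorr <- function(v) {
    v <- v - mean(v)
    d <- sum(v^2)
    if (d == 0) return(0)
    sum(v[-1] * v[-length(v)]) / d
}

## Guard: common wavelength grid.
.checkSameGrid <- function(a, b, what = "wavelength") {
    if (length(a) != length(b) || max(abs(a - b)) > 1e-9 * max(abs(a), 1))
        stop("objects are not on a common ", what, " grid")
    invisible(TRUE)
}
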