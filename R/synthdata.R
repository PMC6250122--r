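## Gaussian-band models of the contributing species (relative extinction
## units; band positions follow the observed transient and stationary
## features: flavin anion maxima at 472/403/367 nm, excited-state
## absorption at ~360/505/700/775 nm, stimulated emission at 545 nm,
## tryptophanyl radical cation bands at ~410 nm and broad 490-700 nm,
## neutral Trp radical ~510 nm, neutral flavin radical redshifted into the
## 550-700 nm region, Trp photoproduct below 400 nm).
.BAND_PRESETS <- list(
    FAD_ox = list(c(365, 50, 0.85), c(425, 20, 0.55), c(447, 22, 1.0),
                  c(475, 20, 0.55)),
    FAD_free = list(c(365, 55, 0.80), c(450, 48, 0.95)),
    FAD_anion = list(c(367, 26, 0.70), c(403, 26, 0.80), c(472, 30, 0.55)),
    FADH_neutral = list(c(358, 50, 0.50), c(585, 70, 0.28),
                        c(624, 60, 0.33)),
    FAD_singlet = list(c(360, 55, 0.90), c(505, 50, 0.70), c(700, 70, 0.45),
                       c(775, 60, 0.50)),
    SE = list(c(545, 80, 0.45)),
    TrpH_cation = list(c(410, 34, 0.45), c(560, 130, 0.60)),
    TrpH_cation1 = list(c(410, 34, 0.45), c(575, 150, 0.60)),
    TrpH_cation23 = list(c(410, 34, 0.45), c(555, 110, 0.60)),
    TrpH_cation4 = list(c(410, 34, 0.50), c(560, 140, 0.65)),
    Trp_neutral = list(c(330, 60, 0.40), c(510, 120, 0.50)),
    TrpX = list(c(355, 70, 0.60)),
    scatter450 = list(c(450, 12, 1.0))
)

#' Species basis spectra as Gaussian-band sums
#'
#' Deterministic model spectra of the photocycle species on a common
#' wavelength grid. Preset names: FAD_ox, FAD_free, FAD_anion,
#' FADH_neutral (the 39 nm redshifted neutral-radical band), FAD_singlet
#' (excited-state absorption), SE (stimulated emission band), TrpH_cation
#' (+ numbered tetrad variants), Trp_neutral, TrpX, scatter450.
#'
#' @param grid wavelength grid, nm (default 340-820 by 4).
#' @param species preset names, or a named list of custom band models
#'   (each a list of c(center, fwhm, amplitude) triples).
#' @return a \linkS4class{BasisSet}.
#' @examples
#' b <- makeSpeciesSpectra(species = c("FAD_ox", "FAD_anion"))
#' @export
makeSpeciesSpectra <- function(grid = seq(340, 820, by = 4),
                               species = c("FAD_ox", "FAD_anion",
                                           "FADH_neutral", "TrpH_cation",
                                           "Trp_neutral", "TrpX",
                                           "FAD_free")) {
    if (is.character(species)) {
        unknown <- setdiff(species, names(.BAND_PRESETS))
        if (length(unknown))
            stop("unknown species presets: ", paste(unknown, collapse = ", "))
        bands <- .BAND_PRESETS[species]
    } else bands <- species
    spectra <- vapply(bands, function(bl) {
        s <- numeric(length(grid))
        for (b in bl) {
            ## a band whose center is more than one FWHM outside the grid
            ## contributes essentially nothing and is worth flagging
            if (b[1] < min(grid) - b[2] || b[1] > max(grid) + b[2])
                warning(sprintf("band at %.0f nm lies outside the grid", b[1]))
            s <- s + .gaussBand(grid, b[1], b[2], b[3])
        }
        s
    }, numeric(length(grid)))
    colnames(spectra) <- names(bands)
    basisSet(grid, spectra)
}

## Difference spectra (species minus oxidized ground state) per compartment
## of a named kinetic preset, on the given grid.
.regimeSpecies <- function(regime, grid) {
    sp <- function(nm) {
        s <- numeric(length(grid))
        for (b in .BAND_PRESETS[[nm]]) s <- s + .gaussBand(grid, b[1], b[2], b[3])
        s
    }
    g <- sp("FAD_ox")
    switch(regime,
        ps = {
            S <- cbind(Sstar = sp("FAD_singlet") - sp("SE") - g,
                       RP1 = sp("FAD_anion") + sp("TrpH_cation1") - g,
                       RP2 = sp("FAD_anion") + sp("TrpH_cation23") - g)
            list(spectra = S, r0 = c(Sstar = 0.37, RP1 = 0.25, RP2 = 0.02))
        },
        us = {
            S <- cbind(RP4 = sp("FAD_anion") + sp("TrpH_cation4") - g,
                       RPd = sp("FAD_anion") + sp("Trp_neutral") - g)
            list(spectra = S, r0 = c(RP4 = 0.03, RPd = 0.02))
        },
        ms = {
            S <- cbind(RPd = sp("FAD_anion") + sp("Trp_neutral") - g,
                       FADanion = sp("FAD_anion") - g)
            list(spectra = S, r0 = c(RPd = 0, FADanion = 0))
        },
        stop("unknown regime: ", regime))
}

## Kinetic scheme of a regime, built from the photocycle parameters.
.regimeModel <- function(regime, p) {
    switch(regime,
        ps = sequentialModel(c("Sstar", "RP1", "RP2"),
                             c(p@tauET1, p@tauET2, Inf),
                             branchToNext = c(1, 1 - p@phiRec, 1)),
        us = sequentialModel(c("RP4", "RPd"), c(p@tauDeprot, Inf)),
        ms = sequentialModel(c("RPd", "FADanion"),
                             c(p@tauTrpDecay, 1 / p@kReox)),
        stop("unknown regime: ", regime))
}

## Instrument defaults per regime: time grid and IRF.
.regimeInstrument <- function(regime) {
    switch(regime,
        ps = list(times = buildTimeAxis("-1ps", "1ps", "3ns", 500),
                  irf = irf(0, fwhm = "100fs")),
        us = list(times = seq(-0.5e-6, 10e-6, by = 0.05e-6),
                  irf = irf(0, fwhm = "100ns")),
        ms = list(times = seq(12.5e-3, 10, by = 12.5e-3),
                  irf = irf(0, fwhm = "10ms")))
}

#' Generate a synthetic TA matrix for one measurement regime
#'
#' Builds \eqn{\Delta A(\lambda, t)} = concentrations x difference spectra
#' for the regime's kinetic scheme (ps: three components with the primary
#' electron-transfer cascade and recombination branching; us: terminal
#' radical-pair deprotonation plus a persistent component; ms: neutral Trp
#' radical decay over a much slower flavin reoxidation), convolved with
#' the regime's Gaussian IRF, optionally chirped/polarized, with pre-t0
#' scatter and seeded i.i.d. Gaussian noise. Ground truth sufficient for
#' bit-identical regeneration is attached.
#'
#' @param regime "ps", "us" or "ms".
#' @param snr peak |dA| to noise sigma ratio (Inf = noise-free).
#' @param seed RNG seed.
#' @param polarization "magic" (default) or "pair" for a
#'   parallel/perpendicular pair built from per-species anisotropies r0.
#' @param params a \linkS4class{PhotocycleParams} holding the generating
#'   rates and branching.
#' @param grid wavelength grid, nm; defaults to the regime's instrument
#'   (340-820 by 4 for ps/us, 400-700 by 10 for ms).
#' @param times optional time grid override, seconds.
#' @param chirp optional \linkS4class{ChirpModel} applied in the raw-data
#'   direction (ps only).
#' @param scatterAmp amplitude of a 450 nm pump-scatter spectrum added at
#'   all delays (0 = none).
#' @return for "magic": list(ta, truth); for "pair": list(par, perp,
#'   magic, truth). truth stores model, spectra, IRF, r0, noise sigma and
#'   seed.
#' @export
generateRegime <- function(regime = c("ps", "us", "ms"), snr = 30, seed = 7,
                           polarization = c("magic", "pair"),
                           params = photocycleParams(), grid = NULL,
                           times = NULL, chirp = NULL, scatterAmp = 0) {
    regime <- match.arg(regime)
    polarization <- match.arg(polarization)
    if (is.null(grid))
        grid <- if (regime == "ms") seq(400, 700, by = 10)
                else seq(340, 820, by = 4)
    inst <- .regimeInstrument(regime)
    if (is.null(times)) times <- inst$times
    times <- asSeconds(times)
    model <- .regimeModel(regime, params)
    spec <- .regimeSpecies(regime, grid)
    C <- concentrationProfiles(model, inst$irf, times)
    pop <- spec$spectra %*% t(C)               # wavelengths x times
    sigma <- if (is.finite(snr)) max(abs(pop)) / snr else 0
    set.seed(seed)
    finish <- function(vals, pol) {
        if (!is.null(chirp)) {
            t0 <- evalChirp(chirp, grid)
            for (i in seq_along(grid)) {
                keep <- times - t0[i]
                vals[i, ] <- stats::approx(times, vals[i, ], xout = keep,
                                           rule = 2)$y
            }
        }
        if (scatterAmp != 0)
            vals <- vals + scatterAmp * .gaussBand(grid, 450, 12, 1)
        if (sigma > 0)
            vals <- vals + matrix(stats::rnorm(length(vals), 0, sigma),
                                  nrow(vals))
        taMatrix(grid, times, vals, polarization = pol,
                 meta = list(regime = regime, seed = seed))
    }
    truth <- list(regime = regime, model = model, spectra = spec$spectra,
                  irf = inst$irf, r0 = spec$r0, sigma = sigma, seed = seed,
                  params = params, lifetimes = {
                      k <- -diag(model@K); ifelse(k > 0, 1 / k, Inf)
                  })
    if (polarization == "magic") {
        list(ta = finish(pop, "magic"), truth = truth)
    } else {
        r <- spec$r0[colnames(C)]
        weighted <- function(f) spec$spectra %*% diag(f, length(r)) %*% t(C)
        par <- weighted(1 + 2 * r)
        perp <- weighted(1 - r)
        list(par = finish(par, "parallel"), perp = finish(perp, "perpendicular"),
             magic = finish(pop, "magic"), truth = truth)
    }
}

#' Forward-generate a streak-camera triplet from a TA matrix
#'
#' Inverse of \code{\link{taFromStreak}}: D_F = lamp + dark,
#' D_FL = dark + lamp 10^-dA, D_0 = dark. Round-trips to the input at
#' machine precision on unmasked cells.
#'
#' @param ta a \linkS4class{TAMatrix} with finite values.
#' @param lamp flash-lamp intensity: scalar or per-wavelength vector (> 0).
#' @param dark dark-count level (scalar, >= 0).
#' @return a \linkS4class{StreakTriplet}.
#' @export
streakFromTA <- function(ta, lamp = 1000, dark = 50) {
    if (any(lamp <= 0)) stop("lamp intensity must be positive")
    nL <- length(ta@wavelengths); nT <- length(ta@times)
    L <- matrix(rep(lamp, length.out = nL), nL, nT)
    D0 <- matrix(dark, nL, nT)
    vals <- ta@values
    vals[!is.finite(vals)] <- 0
    streakTriplet(ta@wavelengths, ta@times,
                  dFL = D0 + L * 10^(-vals), d0 = D0, dF = D0 + L)
}

#' Generate a repeated-illumination stationary-spectrum sequence
#'
#' Emulates the pulsed-illumination experiment: after each blue-light
#' pulse and full dark reoxidation, the absorption spectrum is a mixture
#' of bound oxidized FAD, released free FAD and the accumulated Trp
#' photoproduct, with mole fractions from
#' \code{\link{simulateIllumination}}, plus seeded Gaussian noise. The
#' dark spectrum before any pulse is included as index 0.
#'
#' @param p a \linkS4class{PhotocycleParams}.
#' @param schedule an \linkS4class{IlluminationSchedule}.
#' @param basis optional \linkS4class{BasisSet}; must contain FAD_ox,
#'   FAD_free and TrpX (default: the built-in presets).
#' @param noiseSd absolute noise sigma in OD units of the basis scale.
#' @param seed RNG seed.
#' @return list with \code{spectra} (wavelengths x pulses+1),
#'   \code{pulseIndex} (0..n), \code{wavelengths}, \code{basis},
#'   \code{truth} (the simulation output plus seed/noise).
#' @export
generateIlluminationSequence <- function(p, schedule = standardSchedule(),
                                         basis = NULL, noiseSd = 0.002,
                                         seed = 7) {
    if (is.null(basis))
        basis <- makeSpeciesSpectra(species = c("FAD_ox", "FAD_free", "TrpX"))
    need <- c("FAD_ox", "FAD_free", "TrpX")
    if (!all(need %in% speciesNames(basis)))
        stop("basis must contain ", paste(need, collapse = ", "))
    sim <- simulateIllumination(p, schedule)
    pp <- sim$perPulse
    W <- rbind(c(1, 0, 0),
               cbind(pp$boundFAD, pp$freeFAD, pp$trpX))
    S <- basis@spectra[, need, drop = FALSE]
    vals <- S %*% t(W)
    set.seed(seed)
    if (noiseSd > 0)
        vals <- vals + matrix(stats::rnorm(length(vals), 0, noiseSd),
                              nrow(vals))
    list(spectra = vals, pulseIndex = 0:nrow(pp),
         wavelengths = basis@wavelengths, basis = basis,
         truth = c(sim, list(seed = seed, noiseSd = noiseSd,
                             mixing = W)))
}
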