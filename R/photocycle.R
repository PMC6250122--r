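#' Construct PhotocycleParams
#'
#' Defaults encode the branched flavoprotein photoactivation scheme: sub-ps
#' primary electron transfer (848 fs), decay of the primary radical pair in
#' 46 ps with 20\% recombination to ground, terminal radical-pair formation
#' in the ns gap (default 30 ns, the geometric middle of the 3-100 ns
#' bound), deprotonation of the terminal TrpH radical cation in 1 us, decay
#' of the neutral Trp radical (decomposition) in 187 ms, and O2-dependent
#' reoxidation of the flavin anion radical on the minute scale. The
#' protonation state of the stable flavin radical follows the pocket
#' pH/pKa. \code{excPerSecond} (mean excitations per flavin per second of
#' blue-light illumination) and \code{phiRelease} (per-photon FAD release
#' probability of a Trp-depleted protein) parameterize the repeated-
#' illumination bookkeeping; see the vignette for how the defaults are tied
#' to the observed ~50\% bound-FAD endpoint and 6\% cumulative release
#' yield of the 13-pulse schedule.
#'
#' @param tauET1,tauET2,tauRP4,tauDeprot,tauTrpDecay lifetimes (seconds or
#'   unit strings).
#' @param phiRec recombination branching of the primary radical pair.
#' @param kReox reoxidation rate at unit relative O2, 1/s.
#' @param phiRelease per-photon FAD release probability (Trp-depleted
#'   proteins).
#' @param nTrpSacrificial sacrificial Trp tetrad positions (default 3:
#'   the terminal, third and second position; recombination at the first
#'   is fast).
#' @param pocketPKa,pocketPH flavin radical protonation equilibrium.
#' @param excPerSecond mean excitations per flavin per second of
#'   illumination.
#' @return a \linkS4class{PhotocycleParams}.
#' @export
photocycleParams <- function(tauET1 = "848fs", tauET2 = "46ps",
                             phiRec = 0.2, tauRP4 = "30ns",
                             tauDeprot = "1us", tauTrpDecay = "187ms",
                             kReox = 1 / 180, phiRelease = 0.1609,
                             nTrpSacrificial = 3, pocketPKa = 8,
                             pocketPH = 9, excPerSecond = 0.5 / 0.06 / 30) {
    new("PhotocycleParams", tauET1 = asSeconds(tauET1),
        tauET2 = asSeconds(tauET2), phiRec = phiRec,
        tauRP4 = asSeconds(tauRP4), tauDeprot = asSeconds(tauDeprot),
        tauTrpDecay = asSeconds(tauTrpDecay), kReox = kReox,
        phiRelease = phiRelease, nTrpSacrificial = nTrpSacrificial,
        pocketPKa = pocketPKa, pocketPH = pocketPH,
        excPerSecond = excPerSecond)
}

#' Construct an IlluminationSchedule
#'
#' @param durations pulse durations, seconds (or unit strings).
#' @param energies pulse energies, mJ (informational).
#' @param darkIntervals dark gaps between pulses, seconds; defaults to 900 s
#'   (full reoxidation).
#' @return an \linkS4class{IlluminationSchedule}.
#' @export
illuminationSchedule <- function(durations, energies = 20 * asSeconds(durations),
                                 darkIntervals = rep(900, length(durations))) {
    new("IlluminationSchedule", durations = asSeconds(durations),
        energies = energies, darkIntervals = darkIntervals)
}

#' The 13-pulse repeated-illumination schedule
#'
#' 10 x 1 s, 2 x 5 s and 1 x 10 s blue-light pulses (30 s total) with full
#' dark reoxidation between pulses.
#' @return an \linkS4class{IlluminationSchedule}.
#' @export
standardSchedule <- function()
    illuminationSchedule(c(rep(1, 10), rep(5, 2), 10))

## Bateman amplitudes of an irreversible chain: compartment c has decay
## rate kvec[c] and feeds compartment c+1 with fraction frac[c]. Returns
## the amplitude matrix A with p_c(t) = sum_j A[c, j] * convExp(t, kvec[j]).
.batemanAmplitudes <- function(kvec, frac) {
    n <- length(kvec)
    A <- matrix(0, n, n)
    A[1, 1] <- 1
    if (n > 1) for (c in 2:n) {
        for (j in seq_len(c - 1)) {
            dk <- kvec[c] - kvec[j]
            if (abs(dk) <= 1e-9 * max(kvec[c], kvec[j]))
                stop("chain rates must be pairwise distinct")
            A[c, j] <- A[c - 1, j] * frac[c - 1] * kvec[c - 1] / dk
        }
        A[c, c] <- -sum(A[c, seq_len(c - 1)])
    }
    A
}

#' Simulate a single photocycle shot across all time regimes
#'
#' Propagates unit excited-state population through the branched scheme
#' excited FAD -> primary radical pair -> (recombination | onward electron
#' transfer) -> terminal radical pair -> deprotonation -> Trp radical decay
#' -> flavin anion reoxidation, analytically (each compartment population
#' is a sum of IRF-convolved exponential modes, valid from fs to minutes on
#' one grid). Ground-state returns are split into recombination (intact
#' Trp) and reoxidation after Trp decomposition, so both flavin mass and
#' Trp positional mass are conserved exactly.
#'
#' @param p a \linkS4class{PhotocycleParams}.
#' @param times time grid, seconds (or unit strings); should resolve the
#'   fastest process (an error is raised if the smallest step exceeds a
#'   fifth of the shortest lifetime inside the grid span).
#' @param o2 relative O2 level (1 = aerobic reference).
#' @param irfObj excitation IRF (default: 100 fs FWHM Gaussian at t = 0).
#' @return matrix, times x compartments: FADexc, RP1, RP23, RP4, RPdeprot,
#'   FADanion, FADoxTrpDec (reoxidized, Trp decomposed), groundRec
#'   (recombined, Trp intact).
#' @export
simulateSingleShot <- function(p, times, o2 = 1,
                               irfObj = irf(0, fwhm = "100fs")) {
    validObject(p)
    times <- asSeconds(times)
    kvec <- c(1 / p@tauET1, 1 / p@tauET2, 1 / p@tauRP4, 1 / p@tauDeprot,
              1 / p@tauTrpDecay, p@kReox * o2)
    tauIn <- 1 / kvec[kvec > 0]
    tauIn <- tauIn[tauIn <= diff(range(times)) & tauIn >= 0]
    pos <- times[times > 0]
    if (length(pos) > 1) {
        relevant <- tauIn[tauIn >= min(pos)]
        if (length(relevant) && min(diff(times)) > min(relevant) / 5)
            stop("time grid too coarse to resolve the fastest rate in span")
    }
    frac <- c(1, 1 - p@phiRec, 1, 1, 1, 0)
    A <- .batemanAmplitudes(kvec, frac)
    modes <- vapply(kvec, function(k) convExp(times, k, irfObj),
                    numeric(length(times)))
    pop <- modes %*% t(A)
    step <- convExp(times, 0, irfObj)
    ## absorbing states: integral of k*E_k is (step - E_k), so the flux
    ## integral of a mode sum is analytic.
    intFlux <- function(c, k) {       # integral of k * p_c dt
        v <- numeric(length(times))
        for (j in seq_len(c)) {
            if (A[c, j] == 0) next
            v <- v + A[c, j] / kvec[j] * (step - modes[, j])
        }
        k * v
    }
    groundRec <- p@phiRec * intFlux(2, kvec[2])
    fadOxDec <- if (kvec[6] > 0) intFlux(6, kvec[6]) else numeric(length(times))
    out <- cbind(pop, fadOxDec, groundRec)
    colnames(out) <- c("FADexc", "RP1", "RP23", "RP4", "RPdeprot",
                       "FADanion", "FADoxTrpDec", "groundRec")
    out[abs(out) < 1e-15] <- 0
    out
}

## Dose-domain generator matrix of the Trp-sacrifice / FAD-release chain:
## states q_n .. q_0 (bound protein with n intact sacrificial Trps) and
## "released". s = probability per absorbed photon that a photocycle
## completes (1 - phiRec) and decomposes one Trp.
.releaseGenerator <- function(p) {
    n <- as.integer(p@nTrpSacrificial)
    s <- 1 - p@phiRec
    m <- n + 2L
    M <- matrix(0, m, m)
    for (i in seq_len(n)) {           # q_{n-i+1} -> q_{n-i}
        M[i, i] <- M[i, i] - s
        M[i + 1, i] <- s
    }
    M[n + 1L, n + 1L] <- -p@phiRelease
    M[n + 2L, n + 1L] <- p@phiRelease
    M
}

## expm(M * x) %*% v. Eigendecomposition when well-conditioned; otherwise
## (repeated rates give a defective M, e.g. the equal-rate Trp-sacrifice
## chain) scaling-and-squaring on the Taylor series -- M is tiny.
.expmv <- function(M, x, v) {
    eg <- tryCatch(eigen(M), error = function(e) NULL)
    if (!is.null(eg) && all(abs(Im(eg$values)) < 1e-9) &&
        rcond(Re(eg$vectors)) > 1e-8) {
        V <- Re(eg$vectors)
        return(as.vector(Re(V %*% (exp(Re(eg$values) * x) *
                                       solve(V, v)))))
    }
    A <- M * x
    s <- max(0L, ceiling(log2(max(1, norm(A, "F")))))
    A <- A / 2^s
    E <- diag(nrow(A))
    term <- diag(nrow(A))
    for (i in 1:30) {
        term <- term %*% A / i
        E <- E + term
        if (max(abs(term)) < 1e-18) break
    }
    for (i in seq_len(s)) E <- E %*% E
    as.vector(E %*% v)
}

#' Simulate repeated blue-light illumination with Trp sacrifice
#'
#' Ensemble bookkeeping over an illumination schedule: each absorbed photon
#' of a protein with intact sacrificial Trp positions completes a
#' photocycle with probability 1 - phiRec and decomposes one Trp position
#' (terminal first); proteins with all sacrificial positions decomposed
#' release their FAD with probability phiRelease per absorbed photon. Full
#' dark reoxidation between pulses is assumed. Free FAD still absorbs but
#' is photoinert here, so it counts in the photon balance.
#'
#' @param p a \linkS4class{PhotocycleParams}.
#' @param schedule an \linkS4class{IlluminationSchedule}.
#' @return list with \code{perPulse} (data.frame: pulse, duration, dose,
#'   boundFAD, freeFAD, trpX post-reoxidation mole fractions, and
#'   fadAnionPostPulse / fadhPostPulse directly after the pulse),
#'   \code{absorbedPhotons} (cumulative, per flavin), \code{releasedFAD}
#'   (cumulative fraction) and \code{releaseYield} (their ratio).
#' @export
simulateIllumination <- function(p, schedule) {
    validObject(p); validObject(schedule)
    n <- as.integer(p@nTrpSacrificial)
    M <- .releaseGenerator(p)
    u <- c(1, rep(0, n + 1L))         # all proteins fully intact, bound
    s <- 1 - p@phiRec
    ratio <- 10^(p@pocketPH - p@pocketPKa)   # anion : neutral radical
    nP <- length(schedule@durations)
    rows <- vector("list", nP)
    cumDose <- 0
    for (i in seq_len(nP)) {
        dose <- p@excPerSecond * schedule@durations[i]
        bound_before <- 1 - u[n + 2L]
        u <- .expmv(M, dose, u)
        u[u < 0 & u > -1e-12] <- 0
        cumDose <- cumDose + dose
        released <- u[n + 2L]
        bound <- 1 - released
        ## mean decomposed Trps per protein, scaled to the sacrificial total
        dec <- sum(u[seq_len(n + 1L)] * (n - (n:0))) + released * n
        ## radical population right after the pulse: bound proteins that
        ## completed >= 1 photocycle within this pulse
        radical <- bound * (1 - exp(-s * dose))
        rows[[i]] <- data.frame(
            pulse = i, duration = schedule@durations[i], dose = dose,
            boundFAD = bound, freeFAD = released, trpX = dec / n,
            fadAnionPostPulse = radical * ratio / (1 + ratio),
            fadhPostPulse = radical / (1 + ratio))
    }
    perPulse <- do.call(rbind, rows)
    list(perPulse = perPulse, absorbedPhotons = cumDose,
         releasedFAD = perPulse$freeFAD[nP],
         releaseYield = perPulse$freeFAD[nP] / cumDose)
}

#' Product quantum yields of the photocycle
#'
#' The stable flavin anion radical yield is the excited-state flux not
#' recombining in the ps regime, 1 - phiRec. The free-FAD release yield is
#' operational: cumulative released FAD per cumulative absorbed photon over
#' the illumination schedule.
#'
#' @param p a \linkS4class{PhotocycleParams}.
#' @param schedule an \linkS4class{IlluminationSchedule}.
#' @return list with \code{PhiFADRadical} and \code{PhiFADRelease}.
#' @export
quantumYields <- function(p, schedule = standardSchedule()) {
    sim <- simulateIllumination(p, schedule)
    if (sim$absorbedPhotons <= 0) stop("zero absorbed photons")
    list(PhiFADRadical = 1 - p@phiRec, PhiFADRelease = sim$releaseYield)
}

#' Calibrate the microscopic release probability to a schedule-level yield
#'
#' Finds phiRelease such that the cumulative per-photon release yield of
#' \code{\link{simulateIllumination}} over the given schedule equals
#' \code{targetPhi}.
#'
#' @param targetPhi target cumulative release yield (e.g. 0.06).
#' @param p a \linkS4class{PhotocycleParams} (its phiRelease is ignored).
#' @param schedule an \linkS4class{IlluminationSchedule}.
#' @return calibrated phiRelease.
#' @export
calibrateReleaseYield <- function(targetPhi, p = photocycleParams(),
                                  schedule = standardSchedule()) {
    f <- function(phi) {
        q <- initialize(p, phiRelease = phi)
        simulateIllumination(q, schedule)$releaseYield - targetPhi
    }
    stats::uniroot(f, c(1e-6, 1), tol = 1e-10)$root
}

#' O2-dependent flavin anion reoxidation trace
#'
#' Pseudo-first-order decay of the stable flavin anion radical with rate
#' kReox x o2; anaerobic (o2 = 0) means no decay.
#'
#' @param p a \linkS4class{PhotocycleParams}.
#' @param o2 relative O2 level.
#' @param times time grid, seconds (or unit strings).
#' @return FAD anion population over time (starts at 1).
#' @export
reoxidationTrace <- function(p, o2, times) {
    if (o2 < 0) stop("o2 must be >= 0")
    times <- asSeconds(times)
    exp(-p@kReox * o2 * times)
}

#' Nominal excitation rate from Beer-Lambert dosimetry
#'
#' Order-of-magnitude conversion of pulse power to mean excitations per
#' flavin per second: photon flux times the absorbed fraction divided by
#' the number of chromophores in the illuminated volume.
#'
#' @param odPerCm optical density per cm at the excitation wavelength.
#' @param pathCm illuminated path length, cm.
#' @param powerMW excitation power, mW.
#' @param lambdaNm excitation wavelength, nm.
#' @param volumeUL sample volume, uL.
#' @param epsilon molar extinction at the excitation wavelength,
#'   1/(M cm).
#' @return excitations per chromophore per second.
#' @export
excitationRate <- function(odPerCm, pathCm, powerMW, lambdaNm, volumeUL,
                           epsilon = 11300) {
    conc <- odPerCm / epsilon                       # mol/L
    nChrom <- conc * volumeUL * 1e-6 * 6.02214076e23
    ePhoton <- 6.62607015e-34 * 2.99792458e8 / (lambdaNm * 1e-9)
    photonsPerS <- powerMW * 1e-3 / ePhoton
    absorbed <- 1 - 10^(-odPerCm * pathCm)
    photonsPerS * absorbed / nChrom
}

#' Propagate a kinetic model state by a time step
#'
#' Matrix-exponential propagation p(t + dt) = exp(K dt) p(t) via
#' eigendecomposition; exact for diagonalizable K, so propagating fs to s
#' in one step agrees with stitched propagation at regime boundaries.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param state population vector.
#' @param dt time step, seconds (or unit string).
#' @return propagated population vector.
#' @export
propagateModel <- function(model, state, dt) {
    as.vector(.expmv(model@K, asSeconds(dt), state))
}
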