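## Small deterministic fixtures shared across tests.

## A smooth rank-n matrix: n Gaussian spectra x n exponential decays.
smallRankMatrix <- function(n, wl = seq(400, 700, by = 5),
                            t = seq(0, 5e-9, length.out = 150),
                            noiseSd = 0, seed = 1) {
    centers <- seq(450, 640, length.out = n)
    taus <- 10^seq(log10(5e-10), log10(3e-9), length.out = n)
    S <- vapply(centers, function(c0) exp(-0.5 * ((wl - c0) / 30)^2),
                numeric(length(wl)))
    C <- vapply(taus, function(tau) exp(-t / tau), numeric(length(t)))
    vals <- S %*% t(C)
    if (noiseSd > 0) {
        set.seed(seed)
        vals <- vals + matrix(rnorm(length(vals), 0, noiseSd), nrow(vals))
    }
    taMatrix(wl, t, vals)
}

## A tiny two-component dataset for exact algebra checks.
tinyTwoComponent <- function(noiseSd = 0, seed = 11) {
    wl <- seq(420, 500, by = 20)                  # 5 wavelengths
    t <- seq(-2e-13, 5e-12, length.out = 50)      # 50 times
    b <- kineticBasis(rates = c(2e12, 2e11))
    ir <- irf(0, fwhm = "100fs")
    F <- cbind(convExp(t, 2e12, ir), convExp(t, 2e11, ir))
    Btrue <- rbind(c(1, -0.5, 0.25, 0.8, -0.1),
                   c(0.3, 0.7, -0.2, 0.1, 0.9))
    vals <- t(F %*% Btrue)
    if (noiseSd > 0) {
        set.seed(seed)
        vals <- vals + matrix(rnorm(length(vals), 0, noiseSd), nrow(vals))
    }
    list(ta = taMatrix(wl, t, vals), basis = b, irf = ir, F = F,
         Btrue = Btrue, wl = wl, t = t)
}
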