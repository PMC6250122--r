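test_that("concentration profiles obey the compartment scheme limits", {
    ir <- irf(0, fwhm = "10fs")
    t <- seq(-1e-12, 2e-9, length.out = 2000)
    ## fast feeding, slow drain: intermediate population approaches 1
    m1 <- sequentialModel(c("A", "B", "C"), c("100fs", "100ps", Inf))
    C1 <- concentrationProfiles(m1, ir, t)
    expect_gt(max(C1[, "B"]), 0.98)
    ## 20% recombination: stable-product plateau at 0.8
    m2 <- sequentialModel(c("A", "B"), c("1ps", Inf), branchToNext = c(0.8, 1))
    C2 <- concentrationProfiles(m2, ir, t)
    expect_equal(tail(C2[, "B"], 1), 0.8, tolerance = 1e-9)
    ## no kinetics: the IRF-broadened step
    m3 <- kineticModel("X", matrix(0, 1, 1), 1)
    C3 <- concentrationProfiles(m3, ir, t)
    expect_equal(as.numeric(C3), convExp(t, 0, ir), tolerance = 1e-12)
    ## populations are nonnegative
    expect_true(all(C1 >= 0))
})

test_that("mole conservation holds for closed models at all times", {
    ir <- irf(0, fwhm = "100fs")
    t <- buildTimeAxis("-1ps", "1ps", "3ns", 200)
    m <- sequentialModel(c("A", "B", "C"), c("848fs", "46ps", Inf),
                         branchToNext = c(1, 0.8, 1))
    C <- concentrationProfiles(m, ir, t, ground = TRUE)
    total <- rowSums(C)
    expect_lt(max(abs(total - convExp(t, 0, ir))), 1e-9)
})

test_that("target analysis preserves the chi-square and inverts exactly", {
    g <- generateRegime("ps", snr = 30, seed = 2)
    fit <- fitGlobal(g$ta, kineticBasis(lifetimes = c("500fs", "30ps", Inf)),
                     irf(0, fwhm = "100fs"), multistarts = 3, seed = 1)
    tau <- lifetimes(fit)
    model <- sequentialModel(c("Sstar", "RP1", "RP2"),
                             c(tau[1], tau[2], Inf),
                             branchToNext = c(1, 0.8, 1))
    sr <- sasFromDads(fit, model)
    ## chi-square identical, not merely close
    expect_identical(chisq(sr), chisq(fit))
    ## the amplitude map reproduces the DADS from the SAS exactly
    expect_lt(max(abs(t(sr@amplitudeMap %*% t(sas(sr))) - dads(fit))), 1e-9)
    ## mismatched model rates are refused with both sets listed
    bad <- sequentialModel(c("a", "b", "c"), c("5ps", "1ns", Inf))
    expect_error(sasFromDads(fit, bad), "do not match")
})

test_that("a single-compartment model returns the DADS as its SAS", {
    t <- seq(-1e-12, 1e-9, length.out = 80)
    ir <- irf(0, fwhm = "100fs")
    k <- 1 / 5e-11
    m <- taMatrix(c(450, 550, 650), t,
                  rbind(1, -0.4, 0.2) %*% matrix(convExp(t, k, ir), 1))
    fit <- fitGlobal(m, kineticBasis(rates = k), ir, floatIrfCenter = FALSE,
                     multistarts = 1)
    sr <- sasFromDads(fit, sequentialModel("only", 1 / rates(fit)))
    expect_equal(unname(sas(sr)[, 1]), unname(dads(fit)[, 1]),
                 tolerance = 1e-9)
})

test_that("SAS of sequential synthetic data recover the generating spectra", {
    ## noise-free: exact recovery through the model inversion
    g <- generateRegime("ps", snr = Inf, seed = 1)
    basis <- kineticBasis(lifetimes = g$truth$lifetimes)
    sol <- solveDads(g$ta, basis, g$truth$irf)
    fit <- new("DADSResult", basis = basis, irf = g$truth$irf,
               dads = sol$dads, wavelengths = wavelengths(g$ta),
               times = timePoints(g$ta), chisq = sol$chisq,
               residuals = sol$residuals, convergence = list())
    sr <- sasFromDads(fit, g$truth$model)
    expect_lt(max(abs(sas(sr) - g$truth$spectra)), 1e-8)
    ## noisy: recovery within 1% RMS of the spectral scale
    gn <- generateRegime("ps", snr = 30, seed = 4)
    fn <- fitGlobal(gn$ta, kineticBasis(lifetimes = c("500fs", "30ps", Inf)),
                    irf(0, fwhm = "100fs"), multistarts = 3, seed = 1)
    tau <- lifetimes(fn)
    mod <- sequentialModel(c("Sstar", "RP1", "RP2"), c(tau[1], tau[2], Inf),
                           branchToNext = c(1, 0.8, 1))
    srn <- sasFromDads(fn, mod)
    rms <- sqrt(colMeans((sas(srn) - gn$truth$spectra)^2))
    expect_true(all(rms < 0.01 * max(abs(gn$truth$spectra))))
})

test_that("ground-state addition finds the excited fraction", {
    g <- generateRegime("ps", snr = Inf, seed = 1)
    basis <- kineticBasis(lifetimes = g$truth$lifetimes)
    sol <- solveDads(g$ta, basis, g$truth$irf)
    sd1 <- rowSums(sol$dads)
    groundSpec <- makeSpeciesSpectra(grid = wavelengths(g$ta),
                                     species = "FAD_ox")@spectra[, 1]
    ## fraction 0 is the identity
    expect_equal(addGroundState(sd1, groundSpec, wavelengths(g$ta),
                                fraction = 0)$spectrum, sd1)
    ## the generator's excited fraction is 1; recover within 2%
    est <- addGroundState(sd1, groundSpec, wavelengths(g$ta))
    expect_equal(est$fraction, 1, tolerance = 0.02)
    ## defining property: no bleach left in the ground-state band
    win <- wavelengths(g$ta) >= 430 & wavelengths(g$ta) <= 490
    expect_true(all(est$spectrum[win] > -1e-9))
})

test_that("flavin stripping extracts the mixing coefficient", {
    b <- makeSpeciesSpectra(species = c("FAD_ox", "FAD_anion",
                                        "TrpH_cation23"))
    wl <- wavelengths(b)
    fd <- b@spectra[, "FAD_anion"] - b@spectra[, "FAD_ox"]
    ## flat counter-radical background: exact
    flat <- 0.8 * fd + 0.3
    st <- stripFlavin(flat, fd, wl)
    expect_equal(st$alpha, 0.8, tolerance = 1e-9)
    ## realistic counter-radical: within 1 point
    mix <- 0.8 * (fd + b@spectra[, "TrpH_cation23"])
    st2 <- stripFlavin(mix, fd, wl)
    expect_equal(st2$alpha, 0.8, tolerance = 0.015)
    expect_lt(abs(st2$windowCorrelation), 0.05)
    ## pure difference spectrum strips to zero with alpha 1
    st3 <- stripFlavin(fd, fd, wl)
    expect_equal(st3$alpha, 1, tolerance = 1e-9)
    expect_lt(max(abs(st3$stripped)), 1e-9)
    ## spectrum vanishing in the window gives alpha 0
    outside <- exp(-0.5 * ((wl - 700) / 20)^2)
    expect_equal(stripFlavin(outside, fd, wl)$alpha, 0, tolerance = 1e-9)
    ## a difference spectrum absent from the window is refused
    expect_error(stripFlavin(mix, outside, wl), "~0 inside the window")
})

test_that("recombination fraction maps from the stripping coefficient", {
    expect_equal(estimateRpr(0.8), 0.2)
    expect_equal(estimateRpr(1), 0)
    expect_equal(estimateRpr(1.1), 0)   # noise overshoot clips to 0
    expect_error(estimateRpr(1.5), "admissible")
    expect_error(estimateRpr(-0.1), "admissible")
})
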