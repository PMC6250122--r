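test_that("IRF-convolved exponential has the correct limits and stability", {
    ir <- irf(0, fwhm = "100fs")
    sigma <- ir@width
    ## delta-IRF limit: for t - mu >> sigma, plain exponential
    k <- 1 / 2e-12
    t <- c(1e-12, 2e-12, 3e-12)
    narrow <- irf(0, width = 1e-18)
    expect_equal(convExp(t, k, narrow), exp(-k * t), tolerance = 1e-12)
    ## vanishes long before time zero
    expect_equal(convExp(-1e-11, k, ir), 0, tolerance = 1e-300)
    ## persistent component: half-risen step at the IRF center
    expect_equal(convExp(0, 0, ir), 0.5)
    ## numerically stable at extreme k * sigma (log-erfc path)
    big <- convExp(seq(-1e-12, 1e-11, length.out = 30), 1e16, ir)
    expect_true(all(is.finite(big)))
    expect_true(all(big >= 0))
    ## k * sigma ~ 1e3 still follows the analytic tail
    k3 <- 1e3 / sigma
    tt <- 5 / k3
    expect_gt(convExp(tt + 0, k3, irf(0, width = sigma)), 0)
    expect_error(irf(0, width = -1), "positive")
})

test_that("the linear projection recovers exact amplitudes and satisfies the normal equations", {
    fx <- tinyTwoComponent()
    sol <- solveDads(fx$ta, fx$basis, fx$irf)
    expect_lt(max(abs(sol$dads - t(fx$Btrue))), 1e-10)
    expect_lt(sol$chisq, 1e-20)
    ## with noise: residual orthogonal to the design matrix
    fxn <- tinyTwoComponent(noiseSd = 0.05)
    soln <- solveDads(fxn$ta, fxn$basis, fxn$irf)
    ortho <- t(soln$F) %*% t(soln$residuals)
    expect_lt(max(abs(ortho)), 1e-8 * sqrt(sum(taValues(fxn$ta)^2)))
    ## chi-square is consistent with the reported spectra to machine precision
    rec <- soln$F %*% t(soln$dads)
    expect_equal(soln$chisq, sum((t(taValues(fxn$ta)) - rec)^2),
                 tolerance = 1e-12)
})

test_that("single-component projection matches the hand-computed formula", {
    t <- seq(-5e-13, 5e-12, length.out = 40)
    ir <- irf(0, fwhm = "120fs")
    k <- 1 / 1.3e-12
    f <- convExp(t, k, ir)
    y <- 0.73 * f + c(rep(0, 20), rep(0.001, 20))
    m <- taMatrix(500, t, matrix(y, 1))
    sol <- solveDads(m, kineticBasis(rates = k), ir)
    expect_equal(as.numeric(sol$dads), sum(f * y) / sum(f * f),
                 tolerance = 1e-12)
})

test_that("duplicate rates are rejected with the offending pair named", {
    expect_error(kineticBasis(rates = c(1e12, 1e12)), "not distinct")
    expect_error(kineticBasis(rates = c(0, 0)), "not distinct")
})

test_that("variable projection attains the optimum of the full joint fit", {
    fx <- tinyTwoComponent(noiseSd = 0.05)
    ir <- fx$irf
    ## variable projection route
    vp <- fitGlobal(fx$ta, kineticBasis(rates = c(3e12, 1e11)), ir,
                    floatIrfCenter = FALSE, multistarts = 1)
    ## independent oracle: joint Levenberg-Marquardt over rates AND spectra
    Y <- t(taValues(fx$ta))
    jointRes <- function(par) {
        F <- cbind(convExp(fx$t, 10^par[1], ir), convExp(fx$t, 10^par[2], ir))
        B <- matrix(par[-(1:2)], nrow = 2)
        as.vector(Y - F %*% B)
    }
    set.seed(4)
    start <- c(log10(c(3e12, 1e11)),
               rnorm(10, as.vector(t(fx$Btrue) * 0 + 0.2), 0.3))
    jf <- minpack.lm::nls.lm(start, fn = jointRes,
                             control = minpack.lm::nls.lm.control(
                                 maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    expect_lt(abs(chisq(vp) - jf$deviance), 1e-10)
})

test_that("global fit recovers generating lifetimes within 10% at SNR 30", {
    g <- generateRegime("ps", snr = 30, seed = 7)
    fit <- fitGlobal(g$ta, kineticBasis(lifetimes = c("300fs", "30ps", Inf)),
                     irf(0, fwhm = "100fs"), multistarts = 5, seed = 1)
    tau <- sort(lifetimes(fit)[is.finite(lifetimes(fit))])
    expect_equal(tau[1], 848e-15, tolerance = 0.10)
    expect_equal(tau[2], 46e-12, tolerance = 0.10)
    ## microsecond regime: one decaying plus one persistent component
    gu <- generateRegime("us", snr = 30, seed = 7)
    fu <- fitGlobal(gu$ta, kineticBasis(lifetimes = c("3us", Inf)),
                    irf(0, fwhm = "100ns"), multistarts = 5, seed = 1)
    expect_equal(min(lifetimes(fu)), 1e-6, tolerance = 0.10)
})

test_that("fits are reproducible, scale-equivariant and permutation-invariant", {
    g <- generateRegime("ps", snr = 30, seed = 3)
    init <- kineticBasis(lifetimes = c("500fs", "20ps", Inf))
    ir <- irf(0, fwhm = "100fs")
    f1 <- fitGlobal(g$ta, init, ir, multistarts = 3, seed = 5)
    f2 <- fitGlobal(g$ta, init, ir, multistarts = 3, seed = 5)
    expect_identical(rates(f1), rates(f2))
    expect_identical(dads(f1), dads(f2))
    ## scaling the data scales DADS linearly and chi-square quadratically
    m3 <- taMatrix(wavelengths(g$ta), timePoints(g$ta), 3 * taValues(g$ta))
    f3 <- fitGlobal(m3, init, ir, multistarts = 3, seed = 5)
    expect_equal(dads(f3), 3 * dads(f1), tolerance = 1e-6)
    expect_equal(chisq(f3), 9 * chisq(f1), tolerance = 1e-6)
    ## wavelength order cannot matter: permuting the rows (the labels do
    ## not enter the fit) leaves the chi-square unchanged
    sol <- solveDads(g$ta, f1@basis, f1@irf)
    set.seed(8)
    perm <- sample(length(wavelengths(g$ta)))
    permuted <- taMatrix(wavelengths(g$ta), timePoints(g$ta),
                         taValues(g$ta)[perm, ])
    expect_equal(solveDads(permuted, f1@basis, f1@irf)$chisq, sol$chisq,
                 tolerance = 1e-12)
})

test_that("noise-free data are fit to numerical zero and DADS sum to the excited spectrum", {
    g <- generateRegime("ps", snr = Inf, seed = 1)
    trueTau <- g$truth$lifetimes
    basis <- kineticBasis(lifetimes = trueTau)
    sol <- solveDads(g$ta, basis, g$truth$irf)
    expect_lt(sol$chisq, 1e-16 * sum(taValues(g$ta)^2))
    ## sum of DADS = initially excited species minus ground
    r <- new("DADSResult", basis = basis, irf = g$truth$irf, dads = sol$dads,
             wavelengths = wavelengths(g$ta), times = timePoints(g$ta),
             chisq = sol$chisq, residuals = sol$residuals,
             convergence = list())
    expect_lt(max(abs(sumDads(r) - g$truth$spectra[, "Sstar"])), 1e-9)
})

test_that("a one-component result sums to its own DADS and zero DADS sum to zero", {
    t <- seq(0, 1e-9, length.out = 30)
    ir <- irf(0, fwhm = "1ps")
    m <- taMatrix(c(400, 500), t,
                  rbind(0.5 * convExp(t, 2e9, ir), -0.2 * convExp(t, 2e9, ir)))
    sol <- solveDads(m, kineticBasis(rates = 2e9), ir)
    r <- new("DADSResult", basis = kineticBasis(rates = 2e9), irf = ir,
             dads = sol$dads, wavelengths = c(400, 500), times = t,
             chisq = sol$chisq, residuals = sol$residuals,
             convergence = list())
    expect_equal(sumDads(r), as.numeric(sol$dads))
    r@dads <- r@dads * 0
    expect_equal(sumDads(r), c(0, 0))
})
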