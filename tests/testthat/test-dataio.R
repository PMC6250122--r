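test_that("streak image arithmetic gives decadic difference absorption", {
    wl <- 400:409; t <- seq(0, 9e-6, length.out = 8)
    lamp <- matrix(500, 10, 8); dark <- matrix(20, 10, 8)
    ## no pump effect: D_FL = D_F
    tr <- streakTriplet(wl, t, dFL = dark + lamp, d0 = dark, dF = dark + lamp)
    expect_equal(taValues(taFromStreak(tr)), matrix(0, 10, 8))
    ## transmission ratio 0.1 -> 1 OD
    tr2 <- streakTriplet(wl, t, dFL = dark + 0.1 * lamp, d0 = dark,
                         dF = dark + lamp)
    expect_equal(taValues(taFromStreak(tr2)),
                 matrix(1, 10, 8), tolerance = 1e-12)
    ## nonpositive cells are masked, not fabricated
    bad <- dark + lamp; bad[1, 1] <- 5
    tr3 <- streakTriplet(wl, t, dFL = bad, d0 = dark, dF = dark + lamp)
    expect_true(taMask(taFromStreak(tr3))[1, 1])
    expect_false(any(taMask(taFromStreak(tr3))[-1, ]))
    ## shape mismatch is a structural error
    expect_error(streakTriplet(wl, t, dFL = lamp[, 1:3], d0 = dark, dF = lamp),
                 "axis")
})

test_that("streak generation and inversion round-trip at machine precision", {
    set.seed(42)
    wl <- seq(400, 700, by = 10)
    t <- seq(0, 9e-6, length.out = 25)
    vals <- matrix(rnorm(length(wl) * length(t), 0, 0.2), length(wl))
    ta <- taMatrix(wl, t, vals)
    back <- taFromStreak(streakFromTA(ta, lamp = 1500, dark = 30))
    expect_lt(max(abs(taValues(back) - vals)), 1e-10)
    ## per-wavelength lamp profile
    back2 <- taFromStreak(streakFromTA(ta, lamp = seq(500, 2000,
                                                      length.out = length(wl))))
    expect_lt(max(abs(taValues(back2) - vals)), 1e-10)
})

test_that("pre-t0 scatter subtraction removes per-wavelength offsets and is idempotent", {
    g <- generateRegime("ps", snr = Inf, seed = 1, scatterAmp = 0.05)
    m <- g$ta
    corr <- subtractPreT0(m, "-0.3ps")
    pre <- which(timePoints(corr) <= -0.3e-12)
    expect_gt(length(pre), 3)
    expect_lt(max(abs(rowMeans(taValues(corr)[, pre]))), 1e-14)
    ## scatter-free signal band unchanged: compare against no-scatter truth
    clean <- generateRegime("ps", snr = Inf, seed = 1)$ta
    late <- which(timePoints(corr) > 1e-12)
    expect_lt(max(abs(taValues(corr)[, late] - taValues(clean)[, late])), 1e-12)
    ## idempotent
    twice <- subtractPreT0(corr, "-0.3ps")
    expect_equal(taValues(twice), taValues(corr), tolerance = 1e-14)
    ## all-zero matrix is a fixed point
    z <- taMatrix(400:405, seq(-1e-12, 1e-12, length.out = 10),
                  matrix(0, 6, 10))
    expect_equal(taValues(subtractPreT0(z, "-0.5ps")), matrix(0, 6, 10))
    ## no pre-t0 points is an error
    expect_error(subtractPreT0(m, "-2ps"), "pre-t0")
})

test_that("chirp correction is identity at zero chirp and inverts a known chirp", {
    g <- generateRegime("ps", snr = Inf, seed = 3)
    m <- g$ta
    expect_identical(taValues(chirpCorrect(m, chirpModel(0))),
                     taValues(m))
    ## generate with a linear chirp spanning ~1.5 ps, then correct it
    cm <- chirpModel(c(0, 1.5e-12 / 480), lambda0 = 580)
    raw <- generateRegime("ps", snr = Inf, seed = 3, chirp = cm)$ta
    fixed <- chirpCorrect(raw, cm)
    ok <- !taMask(fixed)
    peak <- max(abs(taValues(m)))
    err <- abs(taValues(fixed) - taValues(m))[ok]
    expect_lt(stats::quantile(err, 0.99), 0.01 * peak)
})

test_that("chirp shifts outside the axis are masked, excessive spread errors", {
    m <- generateRegime("ps", snr = Inf, seed = 3)$ta
    cm <- chirpModel(c(2e-12, 0))   # constant 2 ps shift
    out <- chirpCorrect(m, cm)
    expect_true(any(taMask(out)))
    expect_error(evalChirp(chirpModel(c(0, 1e-12), window = "1ps"),
                           wavelengths(m)),
                 "spread")
})

test_that("quasi-logarithmic time axis weights every decade equally", {
    t <- buildTimeAxis("-1ps", "1ps", "3ns", 500)
    expect_length(t, 500)
    expect_true(all(diff(t) > 0))
    expect_equal(anyDuplicated(t), 0)
    counts <- vapply(list(c(1e-12, 1e-11), c(1e-11, 1e-10), c(1e-10, 1e-9)),
                     function(w) sum(t > w[1] & t <= w[2]), numeric(1))
    expect_lte(diff(range(counts)), 1)
    ## linear segment has about one decade-equivalent of points
    nLin <- sum(t <= 1e-12)
    expect_equal(nLin, counts[1], tolerance = 2)
    ## degenerate request preserves the anchor points
    expect_equal(buildTimeAxis(0, 1, 10, 3), c(0, 1, 10))
    expect_error(buildTimeAxis(1, 0.5, 10, 50), "tMin < tSwitch")
})

test_that("delimited-text matrices round-trip losslessly including the mask", {
    set.seed(9)
    m <- taMatrix(seq(400, 500, 25), c(1e-12, 2e-12, 5e-12),
                  matrix(rnorm(15), 5, 3))
    m@mask[2, 3] <- TRUE
    f <- tempfile(fileext = ".csv")
    writeTAMatrix(m, f)
    back <- readTAMatrix(f)
    expect_equal(wavelengths(back), wavelengths(m))
    expect_equal(timePoints(back), timePoints(m))
    expect_equal(taValues(back)[!taMask(m)], taValues(m)[!taMask(m)])
    expect_true(taMask(back)[2, 3])
    unlink(f)
})

test_that("masked cells never influence a fit", {
    fx <- tinyTwoComponent()
    m <- fx$ta
    sol0 <- solveDads(m, fx$basis, fx$irf)
    ## poison a handful of cells, mask them, refit: identical result
    poisoned <- taValues(m)
    poisoned[1, 5] <- 1e6; poisoned[3, 20] <- -1e6
    msk <- taMask(m); msk[1, 5] <- TRUE; msk[3, 20] <- TRUE
    m2 <- taMatrix(wavelengths(m), timePoints(m), poisoned, mask = msk)
    sol1 <- solveDads(m2, fx$basis, fx$irf)
    expect_equal(sol1$chisq, sol0$chisq, tolerance = 1e-10)
    expect_equal(sol1$dads, sol0$dads, tolerance = 1e-8)
})

test_that("time unit parsing covers the fs-to-minute range", {
    expect_equal(asSeconds(c("848fs", "46ps", "1us", "187ms", "3min")),
                 c(848e-15, 46e-12, 1e-6, 0.187, 180))
    expect_equal(asSeconds(2.5), 2.5)
    expect_error(asSeconds("10fortnights"), "unit")
})
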