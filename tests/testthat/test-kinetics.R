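## Vmax extraction and hue calibration.

times5h <- seq(0, 5, by = 0.1)

test_that("flat and linear curves give the defining Vmax values", {
    flat <- phCurve("s", "LW_NY_25", times5h, rep(6.5, length(times5h)))
    expect_identical(computeVmax(flat), 0)

    lin <- phCurve("s", "LW_NY_25", times5h, 6.5 - 0.5 * times5h)
    expect_equal(computeVmax(lin), -0.5, tolerance = 1e-12)
    ## every window of a line has the same slope, so the window position
    ## cannot matter
    expect_equal(computeVmax(lin, windowPoints = 5L), -0.5,
                 tolerance = 1e-12)
    ## rising pH is not acidification
    up <- phCurve("s", "LW_NY_25", times5h, 4 + 0.3 * times5h)
    expect_identical(computeVmax(up), 0)
})

test_that("window slopes equal the brute-force all-windows regression", {
    set.seed(101)
    for (i in 1:20) {
        r <- runif(1, 0.5, 6); tmid <- runif(1, 1, 4)
        ph <- 4.3 + 2.2 / (1 + exp(r * (times5h - tmid))) +
            rnorm(length(times5h), 0, 0.01)
        cv <- phCurve("s", "DW_YE_30", times5h, ph)
        expect_equal(computeVmax(cv), bruteVmax(times5h, ph),
                     tolerance = 1e-9)
    }
})

test_that("piecewise flat-drop-flat curve matches the enumerated windows", {
    ## flat 1 h at 6.5, linear drop of 0.9 pH over 1 h, flat at 5.6
    tt <- seq(0, 3, by = 0.1)
    ph <- ifelse(tt <= 1, 6.5, ifelse(tt <= 2, 6.5 - 0.9 * (tt - 1), 5.6))
    cv <- phCurve("s", "DW_YE_30", tt, ph)
    expect_equal(computeVmax(cv), bruteVmax(tt, ph), tolerance = 1e-9)
    ## a window fully inside the drop sees slope -0.9; windows straddling
    ## the corners see less, so the extracted Vmax is exactly -0.9
    expect_equal(computeVmax(cv), -0.9, tolerance = 1e-9)
})

test_that("Vmax is invariant to time translation and pH offset, and
           scales inversely with time dilation", {
    set.seed(7)
    ph <- 6.5 - cumsum(abs(rnorm(60, 0.02, 0.01)))
    base <- computeVmax(phCurve("s", "LW_NY_25", seq(0, 5.9, by = 0.1), ph))
    shifted <- computeVmax(phCurve("s", "LW_NY_25",
                                   2 + seq(0, 5.9, by = 0.1), ph + 1))
    expect_equal(base, shifted, tolerance = 1e-12)
    dilated <- computeVmax(phCurve("s", "LW_NY_25",
                                   2 * seq(0, 5.9, by = 0.1), ph))
    expect_equal(dilated, base / 2, tolerance = 1e-12)
})

test_that("endpoint slope method is exposed and differs from OLS on
           curved windows", {
    ## cubic decline: symmetric-window OLS and endpoint slopes disagree
    ## (they coincide on polynomials up to degree 2)
    tt <- seq(0, 2, by = 0.1)
    ph <- 6.5 - 0.15 * tt^3
    cv <- phCurve("s", "LW_NY_25", tt, ph)
    ols <- computeVmax(cv, method = "ols")
    ep <- computeVmax(cv, method = "endpoint")
    expect_lt(ep, 0)
    expect_false(isTRUE(all.equal(ols, ep)))
    ## endpoint slope over a line is still exact
    lin <- phCurve("s", "LW_NY_25", tt, 6.5 - 0.5 * tt)
    expect_equal(computeVmax(lin, method = "endpoint"), -0.5,
                 tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
    expect_error(computeVmax(phCurve("s", "LW_NY_25", seq(0, 0.5, 0.1),
                                     rep(6, 6))), "fewer points")
    hue <- phCurve("s", "LW_NY_25", times5h, rep(90, length(times5h)),
                   valueKind = "hue")
    expect_error(computeVmax(hue), "pH curve")
    expect_error(phCurve("s", "LW_NY_25", c(0, 0.1, 0.3), c(1, 2, 3)),
                 "uniformly spaced")
})

test_that("calibration fit recovers constants and exact quartics", {
    ## constant pH at distinct hues: c0 = 7, higher orders vanish
    cal <- fitHueCalibration(data.frame(hue = seq(30, 80, 10), ph = 7))
    expect_equal(cal@coefficients, c(7, 0, 0, 0, 0), tolerance = 1e-9)

    ## exact quartic recovered against a QR least-squares oracle (hues on
    ## a modest scale so the raw-polynomial basis stays well conditioned)
    true <- c(5.2, -0.3, 0.04, -3e-3, 8e-5)
    h <- seq(2.5, 11.5, length.out = 20)
    ph <- true[1] + true[2]*h + true[3]*h^2 + true[4]*h^3 + true[5]*h^4
    cal2 <- suppressWarnings(
        fitHueCalibration(data.frame(hue = h, ph = ph)))
    X <- cbind(1, h, h^2, h^3, h^4)
    oracle <- unname(drop(qr.solve(X, ph)))
    expect_equal(cal2@coefficients, oracle, tolerance = 1e-6)
    expect_equal(cal2@coefficients, true, tolerance = 1e-6)
    expect_lt(cal2@rmse, 1e-8)
})

test_that("calibration spans pH 6.5-4.0 and flags extrapolated hues", {
    cal <- fitHueCalibration(simulateCalibrationPairs(25, noiseSd = 0))
    expect_true(cal@monotone)
    expect_equal(cal@phRange, c(4.0, 6.6), tolerance = 0.01)
    inside <- phCurve("s", "LW_NY_25", c(0, 0.1, 0.2), c(40, 60, 80),
                      valueKind = "hue")
    outside <- phCurve("s", "LW_NY_25", c(0, 0.1, 0.2), c(10, 60, 150),
                       valueKind = "hue")
    expect_false(any(attr(hueToPh(cal, inside), "extrapolated")))
    expect_equal(attr(hueToPh(cal, outside), "extrapolated"),
                 c(TRUE, FALSE, TRUE))
})

test_that("non-monotone calibration warns but still fits", {
    h <- seq(-3, 3, length.out = 12)
    expect_warning(cal <- fitHueCalibration(data.frame(hue = h, ph = h^2)),
                   "not monotone")
    expect_false(cal@monotone)
})

test_that("too few distinct hues is a rank-deficiency error", {
    expect_error(fitHueCalibration(data.frame(hue = c(1, 1, 2, 2, 3),
                                              ph = 5:1)), "distinct hue")
})

test_that("hue conversion is element-wise and invertible over the range", {
    cal <- defaultCalibration()
    hue <- phCurve("s", "DW_YE_30", seq(0, 1, 0.1),
                   seq(30, 110, length.out = 11), valueKind = "hue")
    ph <- hueToPh(cal, hue)
    expect_identical(ph@valueKind, "pH")
    back <- phToHue(cal, ph@values)
    expect_equal(back, hue@values, tolerance = 1e-6)
    ## wrong kind rejected; empty series passes through
    expect_error(hueToPh(cal, ph), "valueKind")
    empty <- phCurve("s", "DW_YE_30", numeric(), numeric(),
                     valueKind = "hue")
    expect_length(hueToPh(cal, empty)@values, 0L)
})

test_that("phenotype table assembly counts values and missings", {
    tt <- seq(0, 2, by = 0.1)
    curves <- list()
    for (s in c("sA", "sB")) for (cd in conditionIds())
        curves[[paste(s, cd)]] <-
            phCurve(s, cd, tt, 6.5 - runif(1, 0.1, 0.6) * tt)
    curves[["sB DW_YE_40"]] <- NULL
    pt <- buildPhenotypeTable(curves)
    m <- vmaxMatrix(pt)
    expect_equal(dim(m), c(2L, 12L))
    expect_equal(sum(!is.na(m)), 23L)
    expect_true(is.na(m["sB", "DW_YE_40"]))
    ## order invariance
    pt2 <- buildPhenotypeTable(rev(curves))
    expect_identical(vmaxMatrix(pt2), m)
    ## duplicates rejected
    dup <- c(curves, curves[1])
    expect_error(buildPhenotypeTable(dup), "duplicate")
})

test_that("long-form kinetics tables round-trip into curves", {
    tt <- seq(0, 1.5, by = 0.1)
    d <- expand.grid(strain_id = c("x1", "x2"), time_h = tt,
                     stringsAsFactors = FALSE)
    d$temperature_C <- 30; d$volume <- "DW"; d$yeast <- "yes"
    d$value <- 6.5 - 0.4 * d$time_h; d$value_kind <- "pH"
    f <- tempfile(fileext = ".tsv")
    write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
    curves <- readKineticCurves(f)
    expect_length(curves, 2L)
    expect_setequal(vapply(curves, function(cv) cv@strain, ""),
                    c("x1", "x2"))
    expect_true(all(vapply(curves, function(cv) cv@condition, "") ==
                    "DW_YE_30"))
    expect_equal(computeVmax(curves[[1]]), -0.4, tolerance = 1e-9)
})
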