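test_that("fitLogLog recovers exact power-law relations", {
    x <- c(1, 2, 4, 8, 16)
    f1 <- fitLogLog(x, x)
    expect_equal(f1@slope, 1)
    expect_equal(f1@intercept, 0)
    expect_equal(f1@rSquared, 1)
    f2 <- fitLogLog(x^2, x)
    expect_equal(f2@slope, 2)
    expect_error(fitLogLog(c(1, 2), c(1, 2)), "at least 3")
})

test_that("fitLogLog agrees with the normal-equation oracle", {
    # the 5-point fixture
    x <- c(1, 2, 4, 8, 16)
    y <- c(1, 2, 3, 5, 8)
    fit <- fitLogLog(y, x)
    oracle <- bruteOLS(log2(y), log2(x))
    expect_equal(fit@slope, oracle$slope, tolerance = 1e-12)
    expect_equal(fit@intercept, oracle$intercept, tolerance = 1e-12)
    expect_equal(fit@slopeSE, oracle$se, tolerance = 1e-12)
    # random 10-point instances
    set.seed(31)
    for (i in 1:10) {
        xr <- 2^rnorm(10)
        yr <- 2^(0.5 * log2(xr) + rnorm(10, sd = 0.3))
        fr <- fitLogLog(yr, xr)
        or <- bruteOLS(log2(yr), log2(xr))
        expect_equal(fr@slope, or$slope, tolerance = 1e-10)
        expect_equal(fr@slopeSE, or$se, tolerance = 1e-10)
    }
})

test_that("non-positive pairs are excluded pairwise", {
    fit <- fitLogLog(c(1, 2, 4, 0, 8), c(1, 2, 4, 8, 0))
    expect_equal(fit@n, 3L)
    expect_equal(fit@nExcluded, 2L)
    expect_error(fitLogLog(c(0, 0, 0, 1), c(1, 1, 1, 0)), "at least 3")
})

test_that("slopeCI matches the published interval endpoints", {
    fit1 <- new("RegressionFit", slope = 1.108258, intercept = 0,
                slopeSE = 0.003058, df = 12920L, rSquared = 0.9,
                n = 12922L, nExcluded = 0L, label = "")
    ci1 <- slopeCI(fit1, tail = 0.0125)
    expect_equal(unname(ci1), c(1.101403, 1.115113), tolerance = 1e-6)
    fit2 <- new("RegressionFit", slope = 0.986145, intercept = 0,
                slopeSE = 0.001879, df = 12920L, rSquared = 0.9,
                n = 12922L, nExcluded = 0L, label = "")
    ci2 <- slopeCI(fit2, tail = 0.0125)
    expect_equal(unname(ci2), c(0.9819329, 0.9903571), tolerance = 1e-6)
    expect_error(slopeCI(fit1, tail = 0.7), "tail")
    expect_error(slopeCI(fit1, tail = 0), "tail")
})

test_that("slopeCI narrows as the tail grows and as df grows", {
    mkfit <- function(df) new("RegressionFit", slope = 1, intercept = 0,
                              slopeSE = 0.01, df = as.integer(df),
                              rSquared = 0.5, n = as.integer(df + 2),
                              nExcluded = 0L, label = "")
    widths <- vapply(c(0.005, 0.025, 0.1, 0.25, 0.49),
                     function(tl) diff(slopeCI(mkfit(50), tl)), 1)
    expect_true(all(diff(widths) < 0))
    byDf <- vapply(c(5, 20, 100, 5000),
                   function(df) diff(slopeCI(mkfit(df), 0.0125)), 1)
    expect_true(all(diff(byDf) < 0))
    # near the se -> 0 limit the interval collapses onto the slope
    tiny <- new("RegressionFit", slope = 1, intercept = 0,
                slopeSE = 1e-14, df = 100L, rSquared = 0.5, n = 102L,
                nExcluded = 0L, label = "")
    expect_equal(unname(slopeCI(tiny)), c(1, 1), tolerance = 1e-12)
})

test_that("t quantile is close to normal for large df", {
    expect_lt(abs(qt(0.9875, 12920) - qnorm(0.9875)), 3e-4)
})

test_that("compareSlopes is antisymmetric and calibrated", {
    set.seed(11)
    f1 <- fitLogLog(2^rnorm(20, 2, 1), 2^rnorm(20, 2, 1))
    cmpSelf <- compareSlopes(f1, f1)
    expect_equal(cmpSelf@tScore, 0)
    expect_equal(cmpSelf@log10P, 0)
    expect_true(cmpSelf@overlap)

    f2 <- fitLogLog(2^rnorm(20, 1, 2), 2^rnorm(20, 3, 1))
    a <- compareSlopes(f1, f2)
    b <- compareSlopes(f2, f1)
    expect_equal(a@tScore, -b@tScore)
    expect_equal(a@log10P, b@log10P)
    expect_equal(a@overlap, b@overlap)

    # slopes exactly 1.96 joint-SE apart give a two-sided p of ~0.05
    mk <- function(slope, se) new("RegressionFit", slope = slope,
        intercept = 0, slopeSE = se, df = 10000L, rSquared = 0.5,
        n = 10002L, nExcluded = 0L, label = "")
    se1 <- 0.01; se2 <- 0.02
    delta <- qnorm(0.975) * sqrt(se1^2 + se2^2)
    cmp <- compareSlopes(mk(1, se1), mk(1 + delta, se2))
    expect_equal(10^cmp@log10P, 0.05, tolerance = 1e-10)
})

test_that("extreme slope differences keep a finite log10 p-value", {
    mk <- function(slope, se) new("RegressionFit", slope = slope,
        intercept = 0, slopeSE = se, df = 12920L, rSquared = 0.5,
        n = 12922L, nExcluded = 0L, label = "")
    cmp <- compareSlopes(mk(1.108258, 0.003058), mk(0.986145, 0.001879))
    expect_equal(cmp@tScore, -34.02281, tolerance = 1e-5)
    expect_false(cmp@overlap)
    expect_true(is.finite(cmp@log10P))
    expect_lt(cmp@log10P, -200)
})

test_that("pairwisePanel fits the expected panel orientation", {
    sim <- generateTriad(syntheticTruth(nGenes = 4000L, seed = 17L))
    fits <- pairwisePanel(filterExpressed(sim@experiment))
    expect_named(fits, c("TR~RA", "TA~RA", "RA2~RA1"))
    # calibrated generator: TR~RA flattest, TA~RA steepest
    expect_lt(fits[["TR~RA"]]@slope, fits[["RA2~RA1"]]@slope)
    expect_lt(fits[["RA2~RA1"]]@slope, fits[["TA~RA"]]@slope)
    # degenerate generator: all three parameters identical, slopes 1
    degen <- generateTriad(syntheticTruth(nGenes = 300L, sdS = 0, sdT = 0,
                                          defierFraction = 0, nGroups = 0L,
                                          seed = 2L))
    dfits <- pairwisePanel(filterExpressed(degen@experiment))
    expect_equal(dfits[["TR~RA"]]@slope, 1, tolerance = 1e-9)
    expect_equal(dfits[["TA~RA"]]@slope, 1, tolerance = 1e-9)
    tiny <- makeTriad(tr = c(1, 2), ra = c(1, 2), ta = c(1, 2))
    expect_error(suppressWarnings(pairwisePanel(tiny)), "at least 3")
})
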