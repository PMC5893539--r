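#' Ordinary least squares on the log2 scale
#'
#' Fits `log2(y) = intercept + slope * log2(x)` by OLS. Gene pairs in
#' which either value is non-positive or non-finite are excluded
#' pairwise before taking logs (their number is recorded in the
#' `nExcluded` slot).
#'
#' @param y,x paired numeric vectors on the RPKM (linear) scale.
#' @param label optional fit label, e.g. `"TA~RA"`.
#' @param log2Input set `TRUE` when `y` and `x` are already log2 values
#'   (no exclusion or log transform applied).
#' @return a [RegressionFit-class].
#' @examples
#' fitLogLog(c(1, 2, 4, 8), c(1, 2, 4, 8))@slope  # 1
#' @export
fitLogLog <- function(y, x, label = "", log2Input = FALSE) {
    stopifnot(length(y) == length(x))
    if (log2Input) {
        keep <- is.finite(x) & is.finite(y)
        lx <- x[keep]; ly <- y[keep]
    } else {
        keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
        lx <- log2(x[keep]); ly <- log2(y[keep])
    }
    n <- length(lx)
    if (n < 3L) stop("need at least 3 positive pairs, got ", n)
    f <- lm.fit(cbind(`(Intercept)` = 1, slope = lx), ly)
    rss <- sum(f$residuals^2)
    syy <- sum((ly - mean(ly))^2)
    sxx <- sum((lx - mean(lx))^2)
    if (sxx <= 0) stop("regressor has zero variance")
    sigma2 <- rss / (n - 2L)
    methods::new("RegressionFit",
        slope = unname(f$coefficients["slope"]),
        intercept = unname(f$coefficients["(Intercept)"]),
        slopeSE = sqrt(sigma2 / sxx),
        df = n - 2L,
        rSquared = if (syy > 0) 1 - rss / syy else 1,
        n = n, nExcluded = as.integer(sum(!keep)), label = label)
}

setMethod("show", "RegressionFit", function(object) {
    cat(sprintf(
        "RegressionFit%s: slope %.6g (se %.4g), intercept %.4g, R^2 %.4f, n %d\n",
        if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
        object@slope, object@slopeSE, object@intercept,
        object@rSquared, object@n))
})

#' Confidence interval for a regression slope
#'
#' `slope -/+ t_{tail, df} * se` with the Student-t upper-tail quantile.
#' The default tail 0.0125 gives the pair of 97.5% intervals used for
#' the non-overlap comparison of two slopes (a Bonferroni-style pair
#' covering the joint comparison at level 0.05).
#'
#' @param fit a [RegressionFit-class].
#' @param tail upper-tail probability in (0, 0.5).
#' @return numeric `c(lower, upper)`.
#' @examples
#' fit <- new("RegressionFit", slope = 1.108258, intercept = 0,
#'            slopeSE = 0.003058, df = 12920L, rSquared = 0.9,
#'            n = 12922L, nExcluded = 0L, label = "")
#' slopeCI(fit)  # (1.101403, 1.115113)
#' @export
setMethod("slopeCI", "RegressionFit", function(fit, tail = 0.0125) {
    if (!is.finite(tail) || tail <= 0 || tail >= 0.5)
        stop("tail must lie in (0, 0.5)")
    tq <- qt(1 - tail, df = fit@df)
    c(lower = fit@slope - tq * fit@slopeSE,
      upper = fit@slope + tq * fit@slopeSE)
})

#' Compare two regression slopes
#'
#' Computes the per-slope confidence intervals (tail `tail` each), their
#' overlap, and the standardized difference
#' `z = (slope2 - slope1) / sqrt(se1^2 + se2^2)`, which for large df is
#' approximately standard normal. The two-sided p-value is evaluated on
#' the log scale (`pnorm(log.p = TRUE)`), so extreme significance —
#' p-values far below the double-precision underflow threshold — is
#' reported exactly as `log10P`.
#'
#' @param fit1,fit2 [RegressionFit-class] objects.
#' @param tail per-interval upper-tail probability, default 0.0125.
#' @return a [SlopeComparison-class].
#' @export
setMethod("compareSlopes", signature("RegressionFit", "RegressionFit"),
          function(fit1, fit2, tail = 0.0125) {
    ci1 <- slopeCI(fit1, tail)
    ci2 <- slopeCI(fit2, tail)
    tScore <- (fit2@slope - fit1@slope) /
        sqrt(fit1@slopeSE^2 + fit2@slopeSE^2)
    log10P <- (pnorm(-abs(tScore), log.p = TRUE) + log(2)) / log(10)
    methods::new("SlopeComparison",
        ci1 = ci1, ci2 = ci2, ciLevel = 1 - 2 * tail,
        overlap = ci1[["lower"]] <= ci2[["upper"]] &&
                  ci2[["lower"]] <= ci1[["upper"]],
        tScore = tScore, log10P = min(log10P, 0))
})

setMethod("show", "SlopeComparison", function(object) {
    cat(sprintf("SlopeComparison (per-interval level %.3f)\n", object@ciLevel))
    cat(sprintf("  CI 1: (%.6f, %.6f)\n", object@ci1[1], object@ci1[2]))
    cat(sprintf("  CI 2: (%.6f, %.6f)  overlap: %s\n",
                object@ci2[1], object@ci2[2], object@overlap))
    cat(sprintf("  z = %.3f, log10 p = %.2f\n", object@tScore, object@log10P))
})

#' Pairwise regression panel
#'
#' Fits the three log-log regressions that summarize the discrepancy
#' among the parameters: `TR~RA` and `TA~RA` (first symbol is the
#' response) on the canonical profiles, and `RA2~RA1` between the first
#' two RA replicates as the experimental-noise reference. The replicate
#' fit is omitted with a warning when fewer than two RA replicates are
#' stored.
#'
#' @param x a filtered [TriadExperiment-class] on the RPKM scale.
#' @return named list of [RegressionFit-class] objects
#'   (`TR~RA`, `TA~RA`, and `RA2~RA1` when available).
#' @export
pairwisePanel <- function(x) {
    stopifnot(is(x, "TriadExperiment"))
    m <- triadMatrix(x)
    fits <- list(
        "TR~RA" = fitLogLog(m[, "TR"], m[, "RA"], label = "TR~RA"),
        "TA~RA" = fitLogLog(m[, "TA"], m[, "RA"], label = "TA~RA"))
    raReps <- replicateMatrix(x, "RA")
    if (ncol(raReps) >= 2L) {
        fits[["RA2~RA1"]] <- fitLogLog(raReps[, 2], raReps[, 1],
                                       label = "RA2~RA1")
    } else {
        warning("fewer than 2 RA replicates; RA2~RA1 fit omitted")
    }
    fits
}
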