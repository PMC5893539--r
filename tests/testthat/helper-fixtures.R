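# Shared fixture builders for the suite.

makeTriad <- function(tr, ra, ta, geneId = sprintf("g%d", seq_along(tr)),
                      ...) {
    TriadExperiment(tr = tr, ra = ra, ta = ta, geneId = geneId, ...)
}

# A small well-behaved profile with positive values
smallProfile <- function(n = 50, seed = 1) {
    set.seed(seed)
    makeTriad(tr = 2^rnorm(n, 3), ra = 2^rnorm(n, 3), ta = 2^rnorm(n, 3))
}

writeTempCounts <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}

# Brute-force OLS through the normal equations (independent oracle)
bruteOLS <- function(y, x) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    n <- length(y)
    sigma2 <- sum(res^2) / (n - 2)
    se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
    list(intercept = beta[1], slope = beta[2], se = se)
}
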