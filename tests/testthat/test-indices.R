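test_that("computeIndices returns the log2 ratios", {
    te <- makeTriad(tr = c(1, 1, 4), ra = c(1, 2, 2), ta = c(1, 4, 1))
    tab <- computeIndices(te)
    expect_equal(tab@stability, c(0, 1, -1))
    expect_equal(tab@translation, c(0, 1, -1))
    # genes with a zero parameter are excluded
    te0 <- makeTriad(tr = c(1, 0), ra = c(1, 2), ta = c(1, 2))
    expect_equal(length(suppressMessages(computeIndices(te0))@geneId), 1L)
    expect_error(suppressMessages(
        computeIndices(makeTriad(tr = 0, ra = 1, ta = 1))), "no gene")
    # pseudocount path keeps the zero gene
    expect_equal(length(computeIndices(te0, pseudocount = 1)@geneId), 2L)
})

test_that("stability + translation equals log2(TA/TR) exactly", {
    set.seed(13)
    te <- smallProfile(200)
    tab <- computeIndices(te)
    m <- triadMatrix(te)[tab@geneId, ]
    expect_equal(tab@stability + tab@translation,
                 unname(log2(m[, "TA"] / m[, "TR"])), tolerance = 1e-12)
})

test_that("index association is invariant under per-parameter scaling", {
    set.seed(14)
    te <- smallProfile(300)
    a0 <- indexAssociation(computeIndices(te))
    m <- triadMatrix(te)
    for (k in c("TR", "RA", "TA")) {
        m2 <- m
        m2[, k] <- m2[, k] * 7.3
        a <- indexAssociation(computeIndices(
            makeTriad(m2[, "TR"], m2[, "RA"], m2[, "TA"])))
        expect_equal(a$r, a0$r, tolerance = 1e-12)
    }
})

test_that("index association handles the exact and degenerate cases", {
    tab <- new("IndexTable", geneId = c("a", "b", "c"),
               stability = c(1, 2, 3), translation = c(1, 2, 3))
    a <- indexAssociation(tab)
    expect_equal(a$r, 1)
    expect_equal(a$slope, 1)
    tabNeg <- new("IndexTable", geneId = c("a", "b", "c"),
                  stability = c(1, 2, 3), translation = -c(1, 2, 3))
    expect_equal(indexAssociation(tabNeg)$r, -1)
    tabFlat <- new("IndexTable", geneId = c("a", "b", "c"),
                   stability = c(1, 1, 1), translation = c(1, 2, 3))
    expect_error(indexAssociation(tabFlat), "zero-variance")
})

test_that("coupling is recovered from generated data", {
    truth <- syntheticTruth(nGenes = 12000L, rho0 = 0.4,
                            utrEffect = "constant", nGroups = 0L,
                            defierFraction = 0, seed = 8L)
    sim <- generateTriad(truth)
    a <- indexAssociation(computeIndices(filterExpressed(sim@experiment)))
    expect_lt(abs(a$r - 0.4), 0.03)
})

test_that("permutation null is deterministic given the seed", {
    te <- smallProfile(120, seed = 5)
    p1 <- permutationNull(te, nReps = 5L, seed = 99L)
    p2 <- permutationNull(te, nReps = 5L, seed = 99L)
    expect_identical(p1@correlations, p2@correlations)
    p3 <- permutationNull(te, nReps = 1L, seed = 100L)
    expect_false(identical(p1@correlations[1], p3@correlations[1]))
    # shared permutation preserves the TR-TA pairing, a weaker null
    ps <- permutationNull(te, nReps = 5L, seed = 99L, shared = TRUE)
    expect_false(identical(ps@correlations, p1@correlations))
})

test_that("permutation null mean matches the analytic expectation", {
    sim <- generateTriad(syntheticTruth(nGenes = 3000L, seed = 23L))
    prof <- filterExpressed(sim@experiment)
    p <- permutationNull(prof, nReps = 400L, seed = 7L)
    expected <- permutationNullExpectation(prof)
    se <- sd(p@correlations) / sqrt(p@nReps)
    expect_lt(abs(mean(p@correlations) - expected), 3 * se + 3 / 3000)
    expect_true(all(p@correlations < 0))
})

test_that("standardizeProfiles gives exact zero mean and unit sd", {
    te <- smallProfile(100, seed = 6)
    std <- standardizeProfiles(te)
    m <- triadMatrix(std)
    expect_equal(unname(colMeans(m)), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(m, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
    # gene ranking is preserved within each parameter
    raw <- log2(triadMatrix(te))
    for (p in c("TR", "RA", "TA"))
        expect_equal(order(m[, p]), order(raw[, p]))
    expect_error(standardizeProfiles(std), "already standardized")
    expect_error(standardizeProfiles(
        makeTriad(tr = c(1, 1, 1), ra = c(1, 2, 3), ta = c(1, 2, 3))),
        "zero-variance")
})

test_that("standardization attenuates the index correlation", {
    sim <- generateTriad(syntheticTruth(nGenes = 6000L, seed = 31L))
    prof <- filterExpressed(sim@experiment)
    before <- indexAssociation(computeIndices(prof))$r
    after <- indexAssociation(computeIndices(standardizeProfiles(prof)))$r
    expect_lt(after, before)
})

test_that("dispersion summary is exact on degenerate and shifted input", {
    te <- makeTriad(tr = rep(4, 5), ra = rep(2, 5), ta = rep(8, 5))
    d <- dispersionSummary(te)
    expect_equal(d$sd, c(0, 0, 0))
    expect_equal(d$value_range, c(0, 0, 0))
    set.seed(8)
    te2 <- smallProfile(80)
    d1 <- dispersionSummary(te2)
    m <- triadMatrix(te2)
    d2 <- dispersionSummary(makeTriad(2 * m[, "TR"], 2 * m[, "RA"],
                                      2 * m[, "TA"]))
    expect_equal(d1$sd, d2$sd, tolerance = 1e-12)
    expect_equal(d1$value_range, d2$value_range, tolerance = 1e-12)
})

test_that("dispersion increases from TR to RA to TA on generated data", {
    sim <- generateTriad(syntheticTruth(nGenes = 6000L, seed = 12L))
    d <- dispersionSummary(filterExpressed(sim@experiment))
    expect_true(all(diff(d$sd) > 0))
    expect_true(all(diff(d$value_range) > 0))
})

test_that("histogramOverlay conserves counts and aligns peaks", {
    te <- makeTriad(tr = rep(2, 7), ra = rep(4, 7), ta = rep(16, 7))
    h <- histogramOverlay(te, binWidth = 0.5)
    expect_equal(nrow(h), 3L)           # one occupied bin per parameter
    expect_equal(h$count, rep(7L, 3))
    expect_equal(length(unique(h$bin_mid)), 1L)  # aligned peak bins
    set.seed(3)
    te2 <- smallProfile(150)
    h2 <- histogramOverlay(te2, binWidth = 0.25)
    counts <- tapply(h2$count, h2$parameter, sum)
    expect_true(all(counts == 150L))
    expect_error(histogramOverlay(te2, binWidth = 0), "binWidth")
})
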