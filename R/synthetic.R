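#' Ground-truth parameters for the synthetic generator
#'
#' Defaults encode the study conditions the generator emulates: 12000
#' genes; log2 TR centred at RPKM 8 with unit sd; stability-effect and
#' translation-effect scales 0.8 and 0.6 (so dispersion grows
#' TR -> RA -> TA); baseline coupling 0.4 attenuated linearly beyond a
#' UTR proportion of 0.2; Beta(2.2, 2.2) UTR proportions (unimodal,
#' mean 0.5); replicate noise 0.15 on the log2 scale (replicate
#' regression R^2 above 0.94); 30 functional groups of 20 genes; 3%
#' planted defiers.
#'
#' @param nGenes,muTr,sdTr,sdS,sdT,rho0 model scales; see
#'   [SyntheticTruth-class].
#' @param utrEffect coupling curve: `"constant"` (rho(u) = rho0) or
#'   `"linear_decay"` (rho0 up to `decayOnset`, then linear to 0 at
#'   u = 1).
#' @param decayOnset onset u* of the linear decay, default 0.2.
#' @param utrBeta Beta shapes of the UTR-proportion distribution.
#' @param sdRep,nReplicates replicate noise and count.
#' @param nGroups,groupSize,groupShift functional-group structure:
#'   grouped genes share an (s, e) offset of scale `groupShift` and
#'   keep an individual residual of scale `sqrt(1 - groupShift^2)`, so
#'   marginals are preserved while within-group distances shrink.
#' @param defierFraction share of genes planted as defiers (high
#'   stability, low translation, high UTR proportion).
#' @param defierS,defierE mean/sd pairs of the planted defier s and e.
#' @param defierUtrBeta Beta shapes of the defier UTR proportion.
#' @param nPairs similarity pairs generated per source.
#' @param seed RNG seed.
#' @return a [SyntheticTruth-class].
#' @export
syntheticTruth <- function(nGenes = 12000L, muTr = 3, sdTr = 1,
                           sdS = 0.8, sdT = 0.6, rho0 = 0.4,
                           utrEffect = c("linear_decay", "constant"),
                           decayOnset = 0.2, utrBeta = c(2.2, 2.2),
                           sdRep = 0.15, nReplicates = 2L,
                           nGroups = 30L, groupSize = 20L,
                           groupShift = 0.8, defierFraction = 0.03,
                           defierS = c(1.5, 0.3), defierE = c(-2.5, 0.3),
                           defierUtrBeta = c(8, 3), nPairs = 5000L,
                           seed = 1L) {
    methods::new("SyntheticTruth",
        nGenes = as.integer(nGenes), muTr = muTr, sdTr = sdTr,
        sdS = sdS, sdT = sdT, rho0 = rho0,
        utrEffect = match.arg(utrEffect), decayOnset = decayOnset,
        utrBeta = utrBeta, sdRep = sdRep,
        nReplicates = as.integer(nReplicates),
        nGroups = as.integer(nGroups), groupSize = as.integer(groupSize),
        groupShift = groupShift, defierFraction = defierFraction,
        defierS = defierS, defierE = defierE,
        defierUtrBeta = defierUtrBeta, nPairs = as.integer(nPairs),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d genes, rho0 = %g (%s), sdTr/sdS/sdT = %g/%g/%g\n",
        object@nGenes, object@rho0, object@utrEffect,
        object@sdTr, object@sdS, object@sdT))
    cat(sprintf(
        "  %d replicates (sdRep %g), %d groups x %d, defiers %.1f%%, seed %d\n",
        object@nReplicates, object@sdRep, object@nGroups, object@groupSize,
        100 * object@defierFraction, object@seed))
})

#' Coupling curve rho(u)
#'
#' The UTR-dependent coupling between the translation effect and the
#' stability effect: constant `rho0`, or `rho0` up to the onset `u*`
#' followed by linear decay to zero at `u = 1`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param u UTR proportions in [0, 1].
#' @return numeric vector of couplings.
#' @export
rhoCurve <- function(truth, u) {
    if (truth@utrEffect == "constant") return(rep(truth@rho0, length(u)))
    us <- truth@decayOnset
    truth@rho0 * pmax(0, pmin(1, (1 - u) / (1 - us)))
}

# Mixture moments of the latent (s, e) pair: components plain, grouped,
# defier with weights (1-f-gfrac, gfrac, f). Returns means, variances
# and covariance of the mixture.
.latentMoments <- function(truth) {
    f <- truth@defierFraction
    gfrac <- min(1 - f, truth@nGroups * truth@groupSize / truth@nGenes)
    wPlain <- 1 - f - gfrac
    rhobar <- .expectedRho(truth)
    tau2 <- 1 - truth@groupShift^2
    comp <- data.frame(
        w = c(wPlain, gfrac, f),
        muS = c(0, 0, truth@defierS[1]),
        muE = c(0, 0, truth@defierE[1]),
        varS = c(1, 1, truth@defierS[2]^2),
        varE = c(1, 1, truth@defierE[2]^2),
        covSE = c(rhobar, tau2 * rhobar, 0))
    mS <- sum(comp$w * comp$muS)
    mE <- sum(comp$w * comp$muE)
    vS <- sum(comp$w * (comp$varS + comp$muS^2)) - mS^2
    vE <- sum(comp$w * (comp$varE + comp$muE^2)) - mE^2
    cSE <- sum(comp$w * (comp$covSE + comp$muS * comp$muE)) - mS * mE
    list(meanS = mS, meanE = mE, varS = vS, varE = vE, covSE = cSE)
}

.expectedRho <- function(truth) {
    if (truth@utrEffect == "constant") return(truth@rho0)
    f <- function(u) rhoCurve(truth, u) *
        stats::dbeta(u, truth@utrBeta[1], truth@utrBeta[2])
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

#' Expected index coupling under a truth
#'
#' Closed-form correlation between the stability index (`sdS * s`) and
#' the translation index (`sdT * e`) implied by the generative model,
#' accounting for the UTR-dependent coupling curve, the group structure
#' and the planted defiers. For a constant curve without planted
#' structure this equals `rho0`.
#'
#' @param truth a [SyntheticTruth-class].
#' @return a single numeric correlation.
#' @export
expectedCoupling <- function(truth) {
    m <- .latentMoments(truth)
    m$covSE / sqrt(m$varS * m$varE)
}

#' Expected log2 variances under a truth
#'
#' Closed-form variances of the log2 TR, RA, TA profiles:
#' `Var TR = sdTr^2`, `Var RA = sdTr^2 + sdS^2 Var(s)`,
#' `Var TA = Var RA + sdT^2 Var(e) + 2 sdS sdT Cov(s, e)` with the
#' latent mixture moments.
#'
#' @param truth a [SyntheticTruth-class].
#' @return named numeric vector `c(TR=, RA=, TA=)`.
#' @export
expectedLogVariances <- function(truth) {
    m <- .latentMoments(truth)
    vTR <- truth@sdTr^2
    vRA <- vTR + truth@sdS^2 * m$varS
    vTA <- vRA + truth@sdT^2 * m$varE + 2 * truth@sdS * truth@sdT * m$covSE
    c(TR = vTR, RA = vRA, TA = vTA)
}

#' Generate a synthetic triad dataset
#'
#' Draws, per gene: a UTR proportion `u ~ Beta(utrBeta)`; a log2
#' transcription rate `log2 TR ~ N(muTr, sdTr)`; a translation effect
#' `e ~ N(0, 1)`; and a stability effect coupled to translation with
#' UTR-dependent strength,
#' `s = rho(u) e + sqrt(1 - rho(u)^2) z`, `z ~ N(0, 1)`. Then
#' `log2 RA = log2 TR + sdS * s` and `log2 TA = log2 RA + sdT * e` —
#' the stabilization-by-translation mechanism: translationally active
#' mRNAs accumulate (positive s), inactive ones are degraded. Grouped
#' genes share an (s, e) offset (shrunken residuals preserve the
#' marginals); defier genes get (s, e, u) overridden (high stability,
#' low translation, high UTR proportion). Replicates add
#' `N(0, sdRep)` log2 noise around the latent profile, which is stored
#' as the canonical replicate-0 columns. UTR lengths are realized from
#' `u` with a log-normal CDS length and a 5'/3' UTR split of 0.2/0.8;
#' pair-score tables mix true within-group pairs and random pairs with
#' probability equal to the score. Deterministic given the seed.
#'
#' @param truth a [SyntheticTruth-class].
#' @return a [TriadSimulation-class].
#' @examples
#' sim <- generateTriad(syntheticTruth(nGenes = 500L, seed = 7L))
#' sim@experiment
#' @export
setMethod("generateTriad", "SyntheticTruth", function(truth) {
    .withSeed(truth@seed, {
        n <- truth@nGenes
        geneId <- sprintf("G%05d", seq_len(n))
        u <- rbeta(n, truth@utrBeta[1], truth@utrBeta[2])
        x <- rnorm(n, truth@muTr, truth@sdTr)
        e <- rnorm(n)
        z <- rnorm(n)
        # group structure: shared offset + shrunken residual
        # (defier quota reserved so planting always has ungrouped genes)
        nDef <- round(truth@defierFraction * n)
        group <- rep(NA_integer_, n)
        nGrouped <- min(n - nDef, truth@nGroups * truth@groupSize)
        if (truth@nGroups > 0L && nGrouped > 0L) {
            gi <- sample.int(n, nGrouped)
            group[gi] <- rep(seq_len(truth@nGroups),
                             length.out = nGrouped)
        }
        rho <- rhoCurve(truth, u)
        s <- rho * e + sqrt(1 - rho^2) * z
        if (any(!is.na(group))) {
            tau <- sqrt(1 - truth@groupShift^2)
            dS <- rnorm(truth@nGroups, 0, truth@groupShift)
            dE <- rnorm(truth@nGroups, 0, truth@groupShift)
            gi <- which(!is.na(group))
            s[gi] <- dS[group[gi]] + tau * s[gi]
            e[gi] <- dE[group[gi]] + tau * e[gi]
        }
        # planted defiers override the copula (and leave groups)
        defier <- rep(FALSE, n)
        if (nDef > 0L) {
            avail <- which(is.na(group))
            di <- avail[sample.int(length(avail), nDef)]
            defier[di] <- TRUE
            s[di] <- rnorm(nDef, truth@defierS[1], truth@defierS[2])
            e[di] <- rnorm(nDef, truth@defierE[1], truth@defierE[2])
            u[di] <- rbeta(nDef, truth@defierUtrBeta[1],
                           truth@defierUtrBeta[2])
        }
        ltr <- x
        lra <- ltr + truth@sdS * s
        lta <- lra + truth@sdT * e
        reps <- NULL
        if (truth@nReplicates >= 1L) {
            mk <- function(lv) {
                m <- vapply(seq_len(truth@nReplicates), function(k)
                    2^(lv + rnorm(n, 0, truth@sdRep)), numeric(n))
                m
            }
            reps <- list(TR = mk(ltr), RA = mk(lra), TA = mk(lta))
        }
        experiment <- TriadExperiment(tr = 2^ltr, ra = 2^lra, ta = 2^lta,
                                      geneId = geneId, replicates = reps)
        # UTR lengths realizing u (rounded; proportion shifts slightly)
        cds <- pmax(90, round(rlnorm(n, log(1200), 0.45) / 3) * 3)
        uCap <- pmin(u, 0.97)
        utrTotal <- round(cds * uCap / (1 - uCap))
        utr5 <- round(0.2 * utrTotal)
        utr3 <- utrTotal - utr5
        utr <- UtrAnnotation(geneId, utr5 = utr5, utr3 = utr3, cds = cds)
        lengths <- data.frame(gene_id = geneId,
                              exon_length = utr@mrna)
        pairs <- list()
        if (truth@nGroups > 0L && truth@nPairs > 0L) {
            for (src in c("go_similarity", "ppi_confidence"))
                pairs[[src]] <- .generatePairScores(
                    geneId, group, truth@nPairs, src)
        }
        methods::new("TriadSimulation",
            experiment = experiment, utr = utr, lengths = lengths,
            pairs = pairs,
            latent = data.frame(gene_id = geneId, u = u, s = s, e = e,
                                group = group, defier = defier),
            truth = truth)
    })
})

# Pair scores: with probability equal to the score the pair is a true
# within-group pair, otherwise a random pair — so higher-score strata
# hold a larger fraction of functionally related (nearby) genes.
.generatePairScores <- function(geneId, group, nPairs, source) {
    groups <- split(which(!is.na(group)), group[!is.na(group)])
    groups <- groups[vapply(groups, length, 1L) >= 2L]
    n <- length(geneId)
    draw <- nPairs * 3L  # oversample, dedupe, trim
    score <- runif(draw)
    isTrue <- runif(draw) < score & length(groups) > 0
    a <- integer(draw); b <- integer(draw)
    ng <- length(groups)
    for (i in seq_len(draw)) {
        if (isTrue[i]) {
            g <- groups[[sample.int(ng, 1)]]
            ij <- sample(g, 2)
        } else {
            ij <- sample.int(n, 2)
        }
        a[i] <- ij[1]; b[i] <- ij[2]
    }
    key <- .pairKey(geneId[a], geneId[b])
    keep <- !duplicated(key)
    keep <- which(keep)[seq_len(min(nPairs, sum(keep)))]
    PairScoreTable(geneId[a[keep]], geneId[b[keep]], score[keep],
                   source = source)
}

setMethod("show", "TriadSimulation", function(object) {
    cat("TriadSimulation (seed", object@truth@seed, ")\n")
    methods::show(object@truth)
    methods::show(object@experiment)
})

#' Simulate HTSeq-style counts from an RPKM profile
#'
#' Draws `count ~ Poisson(rpkm * length_kb * depth / 1e6)` per gene and
#' sample — the inverse of [rpkm()] in expectation, up to the global
#' library-size renormalization (exact when the input profile satisfies
#' `sum(rpkm * length_kb) == 1e6`).
#'
#' @param x a [TriadExperiment-class] (RPKM scale).
#' @param lengths gene-length data.frame (`gene_id`, `exon_length`).
#' @param depth expected total mapped reads per sample.
#' @param seed RNG seed.
#' @return named list of count data.frames (one per sample column, as
#'   returned by [readCounts()]), keyed `"<parameter>_rep<k>"`.
#' @export
countsFromRpkm <- function(x, lengths, depth = 2e7, seed = 1L) {
    stopifnot(depth > 0)
    a <- SummarizedExperiment::assay(x)
    cd <- SummarizedExperiment::colData(x)
    lenKb <- lengths$exon_length[match(rownames(x), lengths$gene_id)] / 1000
    if (any(is.na(lenKb))) stop("genes missing from the length table")
    out <- list()
    .withSeed(seed, {
        for (j in seq_len(ncol(a))) {
            lam <- a[, j] * lenKb * depth / 1e6
            key <- paste0(cd$parameter[j], "_rep", cd$replicate[j])
            out[[key]] <- data.frame(
                gene_id = rownames(x),
                count = rpois(nrow(a), lam),
                parameter = cd$parameter[j],
                replicate = cd$replicate[j])
        }
    })
    out
}

#' Ground-truth recovery report
#'
#' Runs the analysis pipeline on a generated dataset and compares the
#' results with the generating truth: global index correlation vs the
#' expected coupling, UTR bin curve vs the coupling curve (RMSE),
#' defier recall/precision under the default rectangle, and replicate
#' regression R^2.
#'
#' @param sim a [TriadSimulation-class].
#' @param binEdges UTR bins for the curve comparison.
#' @param stabilityMin,translationMax defier rectangle (defaults as in
#'   [selectDefiers()]).
#' @return list of recovery metrics.
#' @export
truthRecoveryReport <- function(sim, binEdges = seq(0, 1, by = 0.1),
                                stabilityMin = 0, translationMax = -1) {
    stopifnot(is(sim, "TriadSimulation"))
    prof <- filterExpressed(sim@experiment)
    tab <- computeIndices(prof)
    assoc <- indexAssociation(tab)
    expRho <- expectedCoupling(sim@truth)
    curve <- utrBinnedAssociation(tab, sim@utr, binEdges = binEdges)
    rmse <- sqrt(mean((curve$pearson_r -
                       rhoCurve(sim@truth, curve$bin_center))^2))
    sel <- selectDefiers(tab, stabilityMin, translationMax)
    planted <- sim@latent$gene_id[sim@latent$defier]
    recall <- if (length(planted))
        mean(planted %in% sel@geneIds) else NA_real_
    precision <- if (length(sel@geneIds))
        mean(sel@geneIds %in% planted) else NA_real_
    r2 <- tryCatch(replicateConsistency(prof),
                   error = function(e) NULL)
    list(observed_r = assoc$r, expected_r = expRho,
         coupling_abs_error = abs(assoc$r - expRho),
         bin_curve_rmse = rmse,
         defier_recall = recall, defier_precision = precision,
         replicate_r2 = r2,
         n_genes = assoc$n)
}
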