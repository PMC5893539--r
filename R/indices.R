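#' Stability and translation indices
#'
#' Computes, per gene, the stability index `log2(RA/TR)` and the
#' translation index `log2(TA/RA)`. On RPKM-scale data genes with any
#' non-positive parameter are excluded (a configurable pseudocount, off
#' by default, may be added instead); on standardized data (scale
#' `"zlog2"`, see [standardizeProfiles()]) the indices are the plain
#' differences of the standardized log2 profiles. The exact identity
#' `stability + translation == log2(TA/TR)` holds for every gene.
#'
#' @param x a [TriadExperiment-class].
#' @param pseudocount value added to every RPKM before the ratio
#'   (default 0 = exclusion of zeros).
#' @param ... unused.
#' @return an [IndexTable-class].
#' @examples
#' te <- TriadExperiment(tr = 1, ra = 2, ta = 4, geneId = "G1")
#' computeIndices(te)  # stability 1, translation 1
#' @export
setMethod("computeIndices", "TriadExperiment",
          function(x, pseudocount = 0, ...) {
    m <- triadMatrix(x)
    if (S4Vectors::metadata(x)$scale == "zlog2") {
        s <- m[, "RA"] - m[, "TR"]
        tr <- m[, "TA"] - m[, "RA"]
        return(methods::new("IndexTable", geneId = rownames(m),
                            stability = unname(s), translation = unname(tr)))
    }
    m <- m + pseudocount
    keep <- rowSums(m > 0) == 3L
    if (!any(keep)) stop("no gene has all three parameters > 0")
    nd <- sum(!keep)
    if (nd) message(nd, " gene(s) with a non-positive parameter excluded")
    lm2 <- log2(m[keep, , drop = FALSE])
    methods::new("IndexTable",
        geneId = rownames(lm2),
        stability = unname(lm2[, "RA"] - lm2[, "TR"]),
        translation = unname(lm2[, "TA"] - lm2[, "RA"]))
})

setMethod("show", "IndexTable", function(object) {
    cat("IndexTable with", length(object@geneId), "genes\n")
    cat(sprintf("  stability   index: mean %.3f, sd %.3f\n",
                mean(object@stability), sd(object@stability)))
    cat(sprintf("  translation index: mean %.3f, sd %.3f\n",
                mean(object@translation), sd(object@translation)))
})

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "IndexTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene_id = x@geneId, stability_index = x@stability,
               translation_index = x@translation)
})

.olsSlope <- function(y, x) {
    # slope of y on x, moment form
    cov(y, x) / var(x)
}

#' Association between the two indices
#'
#' Correlation between the stability and translation indices and the
#' OLS slope of stability regressed on translation (the orientation of
#' the index scatter); the reverse slope is also reported.
#'
#' @param table an [IndexTable-class] with >= 3 genes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `slope` (stability on translation),
#'   `slopeReverse` (translation on stability) and `n`.
#' @export
indexAssociation <- function(table, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    s <- table@stability
    tr <- table@translation
    if (length(s) < 3L) stop("need at least 3 genes")
    if (sd(s) == 0 || sd(tr) == 0) stop("zero-variance index")
    list(r = cor(s, tr, method = method),
         slope = .olsSlope(s, tr),
         slopeReverse = .olsSlope(tr, s),
         n = length(s))
}

#' Permutation null for the index association
#'
#' Builds the statistical background model for the index association:
#' in each replicate the TR and TA profiles are permuted across genes
#' (two independent permutations by default; `shared = TRUE` applies
#' one common permutation to both) while RA stays fixed, the indices
#' are recomputed, and their correlation and regression slope
#' (stability on translation) recorded. Because RA enters both indices
#' with opposite signs, the null is centred at a negative correlation,
#' approximately
#' `-Var(log2 RA) / sqrt((Var RA + Var TR) (Var RA + Var TA))`.
#' Results are bit-reproducible given `(seed, nReps, gene order)`.
#'
#' @param x a filtered [TriadExperiment-class] (RPKM scale).
#' @param nReps number of permutation replicates, default 1000.
#' @param seed integer RNG seed.
#' @param shared use a single shared permutation for TR and TA.
#' @return a [PermutationResult-class].
#' @export
permutationNull <- function(x, nReps = 1000L, seed = 1L, shared = FALSE) {
    stopifnot(is(x, "TriadExperiment"), nReps >= 1L)
    m <- triadMatrix(x)
    keep <- rowSums(m > 0) == 3L
    lm2 <- log2(m[keep, , drop = FALSE])
    ltr <- lm2[, "TR"]; lra <- lm2[, "RA"]; lta <- lm2[, "TA"]
    n <- length(ltr)
    obsS <- lra - ltr
    obsT <- lta - lra
    cors <- numeric(nReps)
    slopes <- numeric(nReps)
    .withSeed(seed, {
        for (k in seq_len(nReps)) {
            i1 <- sample.int(n)
            i2 <- if (shared) i1 else sample.int(n)
            s <- lra - ltr[i1]
            tr <- lta[i2] - lra
            cors[k] <- cor(s, tr)
            slopes[k] <- .olsSlope(s, tr)
        }
    })
    methods::new("PermutationResult",
        correlations = cors, slopes = slopes, nReps = as.integer(nReps),
        seed = as.integer(seed), shared = shared,
        observedCorrelation = cor(obsS, obsT),
        observedSlope = .olsSlope(obsS, obsT))
}

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("PermutationResult: %d replicates (seed %d%s)\n",
                object@nReps, object@seed,
                if (object@shared) ", shared permutation" else ""))
    cat(sprintf("  observed r = %.4f, slope = %.4f\n",
                object@observedCorrelation, object@observedSlope))
    cat(sprintf("  null r: mean %.4f, range (%.4f, %.4f); positive: %d\n",
                mean(object@correlations), min(object@correlations),
                max(object@correlations), sum(object@correlations > 0)))
})

#' Analytic expectation of the permutation-null correlation
#'
#' Large-n expectation of the permuted index correlation, driven by the
#' shared RA column:
#' `-Var(log2 RA) / sqrt((Var RA + Var TR)(Var RA + Var TA))`, with the
#' variances taken over the genes actually used.
#'
#' @param x the [TriadExperiment-class] handed to [permutationNull()].
#' @return a single numeric value.
#' @export
permutationNullExpectation <- function(x) {
    m <- triadMatrix(x)
    keep <- rowSums(m > 0) == 3L
    lm2 <- log2(m[keep, , drop = FALSE])
    vT <- var(lm2[, "TR"]); vR <- var(lm2[, "RA"]); vA <- var(lm2[, "TA"])
    -vR / sqrt((vR + vT) * (vR + vA))
}

#' Standardize the three profiles
#'
#' Applies the classical standardization — mean subtraction followed by
#' division by the standard deviation — to each log2 profile (TR, RA,
#' TA) across genes, removing the distributional differences among the
#' three parameters. Genes with any non-positive canonical value are
#' excluded first (log undefined). The result is a
#' [TriadExperiment-class] on the `"zlog2"` scale whose indices (see
#' [computeIndices()]) are differences of standardized values.
#'
#' @param x a [TriadExperiment-class] on the RPKM scale.
#' @return a standardized [TriadExperiment-class] (canonical columns
#'   only).
#' @export
standardizeProfiles <- function(x) {
    stopifnot(is(x, "TriadExperiment"))
    if (S4Vectors::metadata(x)$scale != "rpkm")
        stop("profiles are already standardized")
    m <- triadMatrix(x)
    keep <- rowSums(m > 0) == 3L
    if (sum(keep) < 3L) stop("too few genes with all parameters > 0")
    lm2 <- log2(m[keep, , drop = FALSE])
    z <- apply(lm2, 2, function(v) {
        s <- sd(v)
        if (s == 0) stop("zero-variance profile cannot be standardized")
        (v - mean(v)) / s
    })
    TriadExperiment(tr = z[, "TR"], ra = z[, "RA"], ta = z[, "TA"],
                    geneId = rownames(z), scale = "zlog2")
}

#' Dispersion of the three profiles
#'
#' Standard deviation and value range (max - min) of the log2 values of
#' each parameter — the two statistics whose sequential increase from
#' TR to RA to TA quantifies the enhancement of gene expression
#' selectivity along the expression cascade.
#'
#' @param x a filtered [TriadExperiment-class] (RPKM scale); genes with
#'   any non-positive value are excluded.
#' @return data.frame with columns `parameter`, `sd`, `value_range`.
#' @export
dispersionSummary <- function(x) {
    m <- triadMatrix(x)
    keep <- rowSums(m > 0) == 3L
    lm2 <- log2(m[keep, , drop = FALSE])
    data.frame(
        parameter = .PARAMETERS,
        sd = apply(lm2, 2, sd),
        value_range = apply(lm2, 2, function(v) diff(range(v))),
        row.names = NULL)
}

#' Overlaid histograms of the three log2 profiles
#'
#' Bins the log2 values of TR, RA and TA on a common grid. With
#' `align = TRUE` each parameter is shifted so that its modal bin lines
#' up with that of TR, which displays the widening of the distributions
#' without the confounding location differences.
#'
#' @param x a filtered [TriadExperiment-class].
#' @param binWidth histogram bin width on the log2 scale (> 0).
#' @param align shift RA and TA to align modal bins with TR.
#' @return data.frame with columns `parameter`, `bin_mid`, `count`,
#'   `shift` (the shift applied to that parameter).
#' @export
histogramOverlay <- function(x, binWidth = 0.25, align = TRUE) {
    if (!is.finite(binWidth) || binWidth <= 0)
        stop("binWidth must be > 0")
    m <- triadMatrix(x)
    keep <- rowSums(m > 0) == 3L
    lm2 <- log2(m[keep, , drop = FALSE])
    modal <- function(v) {
        b <- floor(v / binWidth)
        tb <- table(b)
        (as.numeric(names(tb)[which.max(tb)]) + 0.5) * binWidth
    }
    refMode <- modal(lm2[, "TR"])
    out <- lapply(.PARAMETERS, function(p) {
        shift <- if (align) refMode - modal(lm2[, p]) else 0
        v <- lm2[, p] + shift
        b <- floor(v / binWidth)
        tb <- table(b)
        data.frame(parameter = p,
                   bin_mid = (as.numeric(names(tb)) + 0.5) * binWidth,
                   count = as.integer(tb), shift = shift)
    })
    do.call(rbind, out)
}
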