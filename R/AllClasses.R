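#' @import methods
#' @importFrom stats cor cov dbeta integrate lm.fit median pnorm pt qnorm qt
#'   quantile rbeta rlnorm rnorm rpois runif sd setNames t.test var
#'   wilcox.test
#' @importFrom utils head read.delim write.table
#' @importFrom graphics hist
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.PARAMETERS <- c("TR", "RA", "TA")

#' Container for matched TR/RA/TA expression profiles
#'
#' `TriadExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] for gene-level RPKM
#' profiles of the three transcriptome parameters: transcription rate
#' (TR, GRO-seq), mRNA abundance (RA, RNA-seq) and translation activity
#' (TA, polysome profiling). Rows are genes; columns are samples.
#' `colData` carries two mandatory columns: `parameter` (one of
#' `"TR"`, `"RA"`, `"TA"`) and `replicate` (integer; replicate `0`
#' denotes the canonical per-parameter profile, replicates `1..k` are
#' biological replicates). The single assay is named after the value
#' scale recorded in `metadata(x)$scale`: `"rpkm"` (non-negative RPKM)
#' or `"zlog2"` (standardized log2 values, see
#' [standardizeProfiles()]).
#'
#' @seealso [TriadExperiment()], [triadMatrix()], [filterExpressed()]
#' @export
setClass("TriadExperiment", contains = "SummarizedExperiment")

setValidity("TriadExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("parameter", "replicate") %in% colnames(cd)))
        return("colData must contain 'parameter' and 'replicate'")
    if (!all(cd$parameter %in% .PARAMETERS))
        return("parameter must be one of TR, RA, TA")
    if (any(cd$replicate < 0) || any(cd$replicate != round(cd$replicate)))
        return("replicate must be a non-negative integer")
    if (anyDuplicated(paste(cd$parameter, cd$replicate)))
        return("duplicated (parameter, replicate) sample")
    if (length(SummarizedExperiment::assays(object)) != 1L)
        return("exactly one assay expected")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% c("rpkm", "zlog2"))
        return("metadata(x)$scale must be 'rpkm' or 'zlog2'")
    a <- SummarizedExperiment::assay(object)
    if (any(!is.finite(a)))
        return("assay values must be finite")
    if (sc == "rpkm" && any(a < 0))
        return("RPKM values must be >= 0")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("unique gene identifiers required as rownames")
    TRUE
})

#' Ordinary least-squares fit on the log2 scale
#'
#' Result of regressing `log2(y)` on `log2(x)` (see [fitLogLog()]).
#'
#' @slot slope,intercept estimated coefficients.
#' @slot slopeSE standard error of the slope.
#' @slot df residual degrees of freedom (`n - 2`).
#' @slot rSquared coefficient of determination.
#' @slot n number of gene pairs used (positive in both variables).
#' @slot nExcluded pairs dropped because either value was non-positive.
#' @slot label optional description, e.g. `"TA~RA"`.
#' @export
setClass("RegressionFit", representation(
    slope = "numeric", intercept = "numeric", slopeSE = "numeric",
    df = "integer", rSquared = "numeric", n = "integer",
    nExcluded = "integer", label = "character"))

setValidity("RegressionFit", function(object) {
    if (object@slopeSE <= 0) return("slopeSE must be > 0")
    if (object@df != object@n - 2L || object@df < 1L)
        return("df must equal n - 2 and be >= 1")
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
        return("rSquared must lie in [0, 1]")
    TRUE
})

#' Two-slope comparison
#'
#' Result of [compareSlopes()]: two per-interval confidence intervals,
#' their overlap status, and the normal-approximation z score
#' `(slope2 - slope1) / sqrt(se1^2 + se2^2)` with its two-sided p-value
#' reported on the log10 scale so that extreme significance (p below
#' 1e-200) remains representable.
#'
#' @slot ci1,ci2 numeric length-2 confidence intervals.
#' @slot ciLevel per-interval coverage (default 0.975).
#' @slot overlap do the two intervals intersect?
#' @slot tScore the standardized slope difference.
#' @slot log10P log10 of the two-sided p-value (always <= 0).
#' @export
setClass("SlopeComparison", representation(
    ci1 = "numeric", ci2 = "numeric", ciLevel = "numeric",
    overlap = "logical", tScore = "numeric", log10P = "numeric"))

setValidity("SlopeComparison", function(object) {
    if (object@ci1[1] >= object@ci1[2] || object@ci2[1] >= object@ci2[2])
        return("interval lower bound must be below upper bound")
    if (object@log10P > 1e-12) return("log10P must be <= 0")
    ovl <- object@ci1[1] <= object@ci2[2] && object@ci2[1] <= object@ci1[2]
    if (!identical(ovl, object@overlap))
        return("overlap flag inconsistent with intervals")
    TRUE
})

#' Per-gene stability and translation indices
#'
#' One row per gene with finite indices: stability index `log2(RA/TR)`
#' (production-vs-abundance discrepancy, an operational proxy for mRNA
#' stability) and translation index `log2(TA/RA)` (polysome loading
#' normalized to abundance). Built by [computeIndices()].
#'
#' @slot geneId character gene identifiers, unique.
#' @slot stability,translation numeric index values.
#' @export
setClass("IndexTable", representation(
    geneId = "character", stability = "numeric", translation = "numeric"))

setValidity("IndexTable", function(object) {
    n <- length(object@geneId)
    if (length(object@stability) != n || length(object@translation) != n)
        return("slot lengths differ")
    if (anyDuplicated(object@geneId)) return("duplicated gene ids")
    if (any(!is.finite(object@stability)) ||
        any(!is.finite(object@translation)))
        return("indices must be finite")
    TRUE
})

#' Permutation null for the index association
#'
#' Holds the observed index correlation/slope and their null
#' distribution obtained by permuting the TR and TA profiles across
#' genes while keeping RA fixed (see [permutationNull()]).
#'
#' @slot correlations,slopes numeric vectors of length `nReps`.
#' @slot nReps number of permutation replicates.
#' @slot seed RNG seed used.
#' @slot shared single shared permutation for TR and TA (default FALSE:
#'   two independent permutations per replicate).
#' @slot observedCorrelation,observedSlope values on the unpermuted data.
#' @export
setClass("PermutationResult", representation(
    correlations = "numeric", slopes = "numeric", nReps = "integer",
    seed = "integer", shared = "logical",
    observedCorrelation = "numeric", observedSlope = "numeric"))

setValidity("PermutationResult", function(object) {
    if (length(object@correlations) != object@nReps ||
        length(object@slopes) != object@nReps)
        return("vectors must have length nReps")
    if (any(abs(object@correlations) > 1 + 1e-12))
        return("correlations must lie in [-1, 1]")
    TRUE
})

#' Per-gene UTR length annotation
#'
#' Lengths (bases) of the 5' UTR, CDS and 3' UTR of one representative
#' mRNA per gene, with the derived mRNA length and UTR proportion
#' `(utr5 + utr3) / mrna`. The identity
#' `mrna == utr5 + cds + utr3` holds exactly.
#'
#' @slot geneId character gene ids.
#' @slot utr5,utr3 UTR lengths, >= 0.
#' @slot cds CDS length, > 0.
#' @slot mrna total mRNA length.
#' @slot proportion UTR proportion in [0, 1).
#' @export
setClass("UtrAnnotation", representation(
    geneId = "character", utr5 = "numeric", utr3 = "numeric",
    cds = "numeric", mrna = "numeric", proportion = "numeric"))

setValidity("UtrAnnotation", function(object) {
    n <- length(object@geneId)
    if (anyDuplicated(object@geneId)) return("duplicated gene ids")
    for (s in c("utr5", "utr3", "cds", "mrna", "proportion"))
        if (length(slot(object, s)) != n) return("slot lengths differ")
    if (any(object@utr5 < 0) || any(object@utr3 < 0))
        return("UTR lengths must be >= 0")
    if (any(object@cds <= 0)) return("CDS length must be > 0")
    if (any(object@mrna != object@utr5 + object@cds + object@utr3))
        return("mrna must equal utr5 + cds + utr3 exactly")
    if (any(object@proportion < 0) || any(object@proportion >= 1))
        return("proportion must lie in [0, 1)")
    TRUE
})

#' Rectangular selection of stabilization-by-translation defiers
#'
#' Genes with high stability index but low translation index — stable
#' yet poorly translated mRNAs escaping stabilization-by-translation.
#' Selected with a closed rectangle by [selectDefiers()].
#'
#' @slot stabilityMin,translationMax rectangle thresholds (inclusive).
#' @slot geneIds selected gene identifiers.
#' @export
setClass("DefierSelection", representation(
    stabilityMin = "numeric", translationMax = "numeric",
    geneIds = "character"))

#' Pairwise gene similarity scores
#'
#' Unordered gene pairs with a similarity or confidence score, e.g.
#' GO-fingerprint similarity or protein-interaction confidence.
#'
#' @slot geneA,geneB gene identifiers (`geneA != geneB`).
#' @slot score finite numeric scores.
#' @slot source `"go_similarity"` or `"ppi_confidence"`.
#' @export
setClass("PairScoreTable", representation(
    geneA = "character", geneB = "character", score = "numeric",
    source = "character"))

setValidity("PairScoreTable", function(object) {
    n <- length(object@geneA)
    if (length(object@geneB) != n || length(object@score) != n)
        return("slot lengths differ")
    if (any(object@geneA == object@geneB))
        return("self pairs not allowed")
    if (any(!is.finite(object@score))) return("scores must be finite")
    key <- ifelse(object@geneA < object@geneB,
                  paste(object@geneA, object@geneB),
                  paste(object@geneB, object@geneA))
    if (anyDuplicated(key)) return("duplicated unordered pairs")
    TRUE
})

#' Index-space distances stratified by similarity score
#'
#' Euclidean distances between gene coordinates in the
#' (stability index, translation index) plane, grouped into score
#' strata plus a background stratum of pairs with no significant
#' similarity. Built by [stratifyDistances()].
#'
#' @slot labels stratum labels, background last.
#' @slot distances named list of numeric distance vectors.
#' @slot backgroundLabel name of the background stratum.
#' @export
setClass("StratifiedDistances", representation(
    labels = "character", distances = "list",
    backgroundLabel = "character"))

#' Ground-truth parameters of the synthetic-data generator
#'
#' Encodes the generative model behind [generateTriad()]: a Gaussian
#' copula on the log2 scale in which translation activity drives mRNA
#' stability with UTR-dependent coupling. See the package vignette for
#' the model and the rationale behind each default.
#'
#' @slot nGenes number of genes.
#' @slot muTr,sdTr location/scale of log2 TR (RPKM).
#' @slot sdS stability-effect scale (log2), the step from TR to RA.
#' @slot sdT translation-effect scale (log2), the step from RA to TA.
#' @slot rho0 baseline stability-translation coupling in [-1, 1].
#' @slot utrEffect `"constant"` or `"linear_decay"` coupling curve.
#' @slot decayOnset UTR proportion u* where linear decay starts.
#' @slot utrBeta Beta shape pair for the UTR-proportion distribution.
#' @slot sdRep replicate noise sd on the log2 scale.
#' @slot nReplicates biological replicates per parameter.
#' @slot nGroups,groupSize,groupShift functional-group structure.
#' @slot defierFraction share of genes planted as defiers.
#' @slot defierS,defierE,defierUtrBeta defier effect distributions.
#' @slot nPairs similarity pairs emitted per source.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticTruth", representation(
    nGenes = "integer", muTr = "numeric", sdTr = "numeric",
    sdS = "numeric", sdT = "numeric", rho0 = "numeric",
    utrEffect = "character", decayOnset = "numeric",
    utrBeta = "numeric", sdRep = "numeric", nReplicates = "integer",
    nGroups = "integer", groupSize = "integer", groupShift = "numeric",
    defierFraction = "numeric", defierS = "numeric", defierE = "numeric",
    defierUtrBeta = "numeric", nPairs = "integer", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    if (object@nGenes < 1L) return("nGenes must be >= 1")
    if (object@sdTr <= 0) return("sdTr must be > 0")
    if (object@sdS < 0 || object@sdT < 0) return("scales must be >= 0")
    if (abs(object@rho0) > 1) return("rho0 must lie in [-1, 1]")
    if (!object@utrEffect %in% c("constant", "linear_decay"))
        return("utrEffect must be 'constant' or 'linear_decay'")
    if (object@decayOnset < 0 || object@decayOnset >= 1)
        return("decayOnset must lie in [0, 1)")
    if (any(object@utrBeta <= 0) || length(object@utrBeta) != 2L)
        return("utrBeta must be two positive shapes")
    if (object@sdRep < 0) return("sdRep must be >= 0")
    if (object@groupShift < 0 || object@groupShift >= 1)
        return("groupShift must lie in [0, 1)")
    if (object@defierFraction < 0 || object@defierFraction > 0.5)
        return("defierFraction must lie in [0, 0.5]")
    TRUE
})

#' A generated dataset together with its ground truth
#'
#' Value of [generateTriad()]: the expression profiles, the UTR
#' annotation, gene lengths for count simulation, similarity pair
#' scores, the latent per-gene variables, and the truth object.
#'
#' @slot experiment a [TriadExperiment-class].
#' @slot utr a [UtrAnnotation-class].
#' @slot lengths data.frame (gene_id, exon_length).
#' @slot pairs list of two [PairScoreTable-class] objects
#'   (`go_similarity`, `ppi_confidence`); empty list when no groups.
#' @slot latent data.frame of per-gene latent variables
#'   (u, s, e, group, defier).
#' @slot truth the [SyntheticTruth-class] used.
#' @export
setClass("TriadSimulation", representation(
    experiment = "TriadExperiment", utr = "UtrAnnotation",
    lengths = "data.frame", pairs = "list", latent = "data.frame",
    truth = "SyntheticTruth"))
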