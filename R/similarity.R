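#' Construct a PairScoreTable
#'
#' @param geneA,geneB character gene ids (`geneA != geneB`; unordered
#'   pairs must be unique).
#' @param score finite numeric similarity/confidence scores.
#' @param source `"go_similarity"` or `"ppi_confidence"`.
#' @return a [PairScoreTable-class].
#' @export
PairScoreTable <- function(geneA, geneB, score,
                           source = c("go_similarity", "ppi_confidence")) {
    source <- match.arg(source)
    methods::new("PairScoreTable", geneA = as.character(geneA),
                 geneB = as.character(geneB), score = as.numeric(score),
                 source = source)
}

setMethod("show", "PairScoreTable", function(object) {
    cat(sprintf("PairScoreTable (%s): %d pairs, score range (%.3g, %.3g)\n",
                object@source, length(object@geneA),
                min(object@score), max(object@score)))
})

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "PairScoreTable",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene_a = x@geneA, gene_b = x@geneB, score = x@score,
               source = x@source)
})

#' Read a pair-score table
#'
#' Tab-separated file with header columns `gene_a`, `gene_b`, `score` —
#' e.g. precomputed GO-fingerprint similarity scores, or protein
#' interaction pairs with their confidence.
#'
#' @param path file path.
#' @param source `"go_similarity"` or `"ppi_confidence"`.
#' @return a [PairScoreTable-class].
#' @export
readPairScores <- function(path,
                           source = c("go_similarity", "ppi_confidence")) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_a", "gene_b", "score")
    if (!all(need %in% colnames(df)))
        stop("expected columns: ", paste(need, collapse = ", "))
    PairScoreTable(df$gene_a, df$gene_b, df$score, source = match.arg(source))
}

#' Distance between two genes in index space
#'
#' Euclidean distance between the (stability index, translation index)
#' coordinates of two genes.
#'
#' @param table an [IndexTable-class].
#' @param geneA,geneB gene identifiers present in `table`.
#' @return non-negative numeric distance.
#' @examples
#' tab <- new("IndexTable", geneId = c("a", "b"),
#'            stability = c(0, 3), translation = c(0, 4))
#' pairDistance(tab, "a", "b")  # 5
#' @export
pairDistance <- function(table, geneA, geneB) {
    i <- match(c(geneA, geneB), table@geneId)
    if (is.na(i[1])) stop("gene not in index table: ", geneA)
    if (is.na(i[2])) stop("gene not in index table: ", geneB)
    sqrt(diff(table@stability[i])^2 + diff(table@translation[i])^2)
}

.distForPairs <- function(table, ia, ib) {
    sqrt((table@stability[ia] - table@stability[ib])^2 +
         (table@translation[ia] - table@translation[ib])^2)
}

#' Stratify index-space distances by similarity score
#'
#' Splits the scored gene pairs into score strata (bins
#' `[e_k, e_{k+1})`, last bin right-closed) and computes the Euclidean
#' distance of each pair in the (stability, translation) plane. A
#' background stratum collects pairs with no significant similarity:
#' listed pairs scoring below the lowest edge, plus unlisted gene pairs
#' drawn either exhaustively (when the number of gene pairs is at most
#' `maxExact`) or as a seeded random subsample of size `nBackground`.
#'
#' @param table an [IndexTable-class].
#' @param pairs a [PairScoreTable-class]; pairs with either gene absent
#'   from `table` are dropped.
#' @param scoreBins increasing numeric bin edges.
#' @param nBackground background subsample size, default 1e6.
#' @param maxExact enumerate all pairs exactly when
#'   `choose(n, 2) <= maxExact` (default 2e5).
#' @param seed RNG seed for the background subsample.
#' @return a [StratifiedDistances-class].
#' @export
stratifyDistances <- function(table, pairs,
                              scoreBins = c(0.25, 0.5, 0.75, 1),
                              nBackground = 1e6, maxExact = 2e5,
                              seed = 1L) {
    stopifnot(is(table, "IndexTable"), is(pairs, "PairScoreTable"))
    if (is.unsorted(scoreBins, strictly = TRUE))
        stop("scoreBins must be strictly increasing")
    ia <- match(pairs@geneA, table@geneId)
    ib <- match(pairs@geneB, table@geneId)
    ok <- !is.na(ia) & !is.na(ib)
    if (any(!ok))
        message(sum(!ok), " pair(s) with genes absent from the index ",
                "table dropped")
    ia <- ia[ok]; ib <- ib[ok]
    score <- pairs@score[ok]
    d <- .distForPairs(table, ia, ib)
    nb <- length(scoreBins) - 1L
    labels <- c(vapply(seq_len(nb), function(k)
        sprintf("[%g,%g%s", scoreBins[k], scoreBins[k + 1],
                if (k == nb) "]" else ")"), ""),
        "background")
    strata <- vector("list", nb + 1L)
    names(strata) <- labels
    for (k in seq_len(nb)) {
        inBin <- score >= scoreBins[k] &
            (if (k == nb) score <= scoreBins[k + 1]
             else score < scoreBins[k + 1])
        strata[[k]] <- d[inBin]
        if (!sum(inBin)) warning("empty stratum: ", labels[k])
    }
    # background: low-scoring listed pairs + unlisted random/exhaustive pairs
    low <- d[score < scoreBins[1]]
    n <- length(table@geneId)
    listedKey <- .pairKey(table@geneId[ia], table@geneId[ib])
    if (n * (n - 1) / 2 <= maxExact) {
        cmb <- utils::combn(n, 2)
        key <- .pairKey(table@geneId[cmb[1, ]], table@geneId[cmb[2, ]])
        keep <- !key %in% listedKey
        bgd <- .distForPairs(table, cmb[1, keep], cmb[2, keep])
    } else {
        bgd <- .withSeed(seed, {
            i1 <- sample.int(n, nBackground, replace = TRUE)
            i2 <- sample.int(n, nBackground, replace = TRUE)
            keep <- i1 != i2 &
                !.pairKey(table@geneId[i1], table@geneId[i2]) %in% listedKey
            .distForPairs(table, i1[keep], i2[keep])
        })
    }
    strata[["background"]] <- c(low, bgd)
    methods::new("StratifiedDistances", labels = labels,
                 distances = strata, backgroundLabel = "background")
}

setMethod("show", "StratifiedDistances", function(object) {
    cat("StratifiedDistances with", length(object@labels), "strata\n")
    for (l in object@labels)
        cat(sprintf("  %-14s n = %7d, median = %s\n", l,
                    length(object@distances[[l]]),
                    if (length(object@distances[[l]]))
                        sprintf("%.4f", median(object@distances[[l]]))
                    else "NA"))
})

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "StratifiedDistances",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
        stratum = x@labels,
        n = vapply(x@distances[x@labels], length, 1L),
        median = vapply(x@distances[x@labels], function(v)
            if (length(v)) median(v) else NA_real_, 1))
})

#' Location test of each stratum against the background
#'
#' One-sided Mann-Whitney rank-sum test per stratum, alternative:
#' stratum distances are smaller than background distances (functionally
#' related genes lie closer in index space). The rank-sum test is used
#' because pairwise-distance distributions are right-skewed.
#'
#' @param strata a [StratifiedDistances-class].
#' @return data.frame with `stratum`, `n`, `median`, `p_value`
#'   (background row has `p_value` NA).
#' @export
stratumShiftTest <- function(strata) {
    stopifnot(is(strata, "StratifiedDistances"))
    bg <- strata@distances[[strata@backgroundLabel]]
    if (!length(bg)) stop("background stratum is empty")
    df <- as.data.frame(strata)
    df$p_value <- NA_real_
    for (l in setdiff(strata@labels, strata@backgroundLabel)) {
        v <- strata@distances[[l]]
        if (length(v))
            df$p_value[df$stratum == l] <-
                wilcox.test(v, bg, alternative = "less")$p.value
    }
    df
}
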