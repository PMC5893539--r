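#' Construct a TriadExperiment
#'
#' Builds the central container from per-parameter RPKM vectors and, if
#' available, per-replicate RPKM matrices. The canonical per-parameter
#' profile is stored as replicate 0; biological replicates as
#' replicates 1..k.
#'
#' @param tr,ra,ta numeric RPKM vectors (canonical profiles), same
#'   length and gene order. Any may be omitted when `replicates` supply
#'   that parameter (the canonical profile is then pooled on demand by
#'   [triadMatrix()]).
#' @param geneId character vector of unique gene identifiers.
#' @param replicates optional named list (`TR`, `RA`, `TA`) of numeric
#'   matrices, genes x replicates, on the RPKM scale.
#' @param scale `"rpkm"` (default) or `"zlog2"`.
#' @param poolMethod how [triadMatrix()] pools replicate RPKMs when a
#'   canonical column is absent: `"mean"` (default) of replicate RPKMs.
#' @return a [TriadExperiment-class].
#' @examples
#' te <- TriadExperiment(tr = c(1, 2), ra = c(2, 4), ta = c(4, 8),
#'                       geneId = c("G1", "G2"))
#' triadMatrix(te)
#' @export
TriadExperiment <- function(tr = NULL, ra = NULL, ta = NULL, geneId,
                            replicates = NULL, scale = c("rpkm", "zlog2"),
                            poolMethod = "mean") {
    scale <- match.arg(scale)
    stopifnot(is.character(geneId), !anyDuplicated(geneId))
    n <- length(geneId)
    cols <- list()
    param <- character(0)
    repl <- integer(0)
    canon <- list(TR = tr, RA = ra, TA = ta)
    for (p in .PARAMETERS) {
        v <- canon[[p]]
        if (!is.null(v)) {
            stopifnot(length(v) == n)
            cols[[length(cols) + 1L]] <- as.numeric(v)
            param <- c(param, p)
            repl <- c(repl, 0L)
        }
        if (!is.null(replicates) && !is.null(replicates[[p]])) {
            m <- as.matrix(replicates[[p]])
            stopifnot(nrow(m) == n)
            for (j in seq_len(ncol(m))) {
                cols[[length(cols) + 1L]] <- m[, j]
                param <- c(param, p)
                repl <- c(repl, j)
            }
        }
    }
    if (!length(cols))
        stop("at least one parameter column is required")
    a <- do.call(cbind, cols)
    rownames(a) <- geneId
    colnames(a) <- ifelse(repl == 0L, param, paste0(param, "_rep", repl))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = setNames(list(a), scale),
        colData = S4Vectors::DataFrame(parameter = param, replicate = repl,
                                       row.names = colnames(a)))
    S4Vectors::metadata(se)$scale <- scale
    S4Vectors::metadata(se)$poolMethod <- poolMethod
    methods::new("TriadExperiment", se)
}

#' Canonical genes-by-parameter matrix
#'
#' Returns the genes x 3 matrix of canonical TR, RA, TA values. For
#' each parameter the replicate-0 column is used when present;
#' otherwise replicate RPKMs are pooled (mean of replicate RPKMs by
#' default, recorded in `metadata(x)$poolMethod`).
#'
#' @param x a [TriadExperiment-class].
#' @param ... unused.
#' @return numeric matrix with columns `TR`, `RA`, `TA`.
#' @export
setMethod("triadMatrix", "TriadExperiment", function(x, ...) {
    cd <- SummarizedExperiment::colData(x)
    a <- SummarizedExperiment::assay(x)
    out <- matrix(NA_real_, nrow(x), 3,
                  dimnames = list(rownames(x), .PARAMETERS))
    for (p in .PARAMETERS) {
        canon <- which(cd$parameter == p & cd$replicate == 0L)
        if (length(canon) == 1L) {
            out[, p] <- a[, canon]
        } else {
            reps <- which(cd$parameter == p & cd$replicate > 0L)
            if (!length(reps))
                stop("no data for parameter ", p)
            out[, p] <- rowMeans(a[, reps, drop = FALSE])
        }
    }
    out
})

#' Replicate matrix for one parameter
#'
#' @param x a [TriadExperiment-class].
#' @param parameter one of `"TR"`, `"RA"`, `"TA"`.
#' @return genes x replicates matrix (replicates 1..k only), or a
#'   0-column matrix when no replicates are stored.
#' @export
replicateMatrix <- function(x, parameter) {
    parameter <- match.arg(parameter, .PARAMETERS)
    cd <- SummarizedExperiment::colData(x)
    idx <- which(cd$parameter == parameter & cd$replicate > 0L)
    idx <- idx[order(cd$replicate[idx])]
    SummarizedExperiment::assay(x)[, idx, drop = FALSE]
}

setMethod("show", "TriadExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("TriadExperiment with", nrow(object), "genes,",
        ncol(object), "samples\n")
    for (p in .PARAMETERS) {
        k <- sum(cd$parameter == p & cd$replicate > 0L)
        canon <- any(cd$parameter == p & cd$replicate == 0L)
        cat(sprintf("  %s: %s%d replicate(s)\n", p,
                    if (canon) "canonical profile + " else "", k))
    }
    cat("  scale:", S4Vectors::metadata(object)$scale, "\n")
    fr <- S4Vectors::metadata(object)$filter
    if (!is.null(fr))
        cat(sprintf("  expressed-gene filter: cutoff %g, retained %d\n",
                    fr$cutoff, fr$retained))
})

#' Filter to expressed genes
#'
#' Retains genes whose canonical RPKM reaches `cutoff` in at least
#' `minParams` of the three parameters. With the defaults (cutoff 1
#' RPKM in at least one parameter) this is the expressed-gene
#' definition used throughout the analysis; the filter report is
#' stored in `metadata(x)$filter`.
#'
#' @param x a [TriadExperiment-class] on the RPKM scale.
#' @param cutoff RPKM threshold (inclusive), default 1.
#' @param minParams minimum number of parameters at or above the
#'   cutoff, default 1.
#' @return the filtered [TriadExperiment-class].
#' @examples
#' te <- TriadExperiment(tr = c(0.5, 2), ra = c(0.2, 1), ta = c(0.1, 9),
#'                       geneId = c("low", "ok"))
#' filterExpressed(te)
#' @export
filterExpressed <- function(x, cutoff = 1, minParams = 1L) {
    stopifnot(is(x, "TriadExperiment"))
    if (S4Vectors::metadata(x)$scale != "rpkm")
        stop("filterExpressed expects RPKM-scale data")
    m <- triadMatrix(x)
    keep <- rowSums(m >= cutoff) >= minParams
    out <- x[keep, ]
    S4Vectors::metadata(out)$filter <- list(
        cutoff = cutoff, minParams = as.integer(minParams),
        retained = sum(keep), dropped = sum(!keep))
    out
}

#' Replicate consistency on the log2 scale
#'
#' For each parameter, regresses log2 of replicate 2 on log2 of
#' replicate 1 (genes with a zero in either replicate are excluded, and
#' the exclusion count is attached as an attribute) and reports the
#' regression R-squared — the replicate-agreement statistic used to
#' check that biological replicates are consistent (R^2 >= 0.94 in
#' well-behaved data).
#'
#' @param x a [TriadExperiment-class] with >= 2 replicates for every
#'   parameter.
#' @return named numeric vector of per-parameter R-squared values, with
#'   attribute `nExcluded` (genes dropped per parameter).
#' @export
replicateConsistency <- function(x) {
    stopifnot(is(x, "TriadExperiment"))
    r2 <- setNames(numeric(3), .PARAMETERS)
    nex <- setNames(integer(3), .PARAMETERS)
    for (p in .PARAMETERS) {
        m <- replicateMatrix(x, p)
        if (ncol(m) < 2L)
            stop("parameter ", p, " has fewer than 2 replicates")
        ok <- m[, 1] > 0 & m[, 2] > 0
        nex[p] <- sum(!ok)
        if (sum(ok) < 3L)
            stop("fewer than 3 genes with positive values in both ",
                 p, " replicates")
        fit <- fitLogLog(m[ok, 2], m[ok, 1], label = paste0(p, "2~", p, "1"))
        r2[p] <- fit@rSquared
    }
    structure(r2, nExcluded = nex)
}
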