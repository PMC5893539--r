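#' Read an HTSeq-count style two-column count file
#'
#' Parses a tab-separated `gene_id<TAB>count` file as written by
#' htseq-count. Summary rows whose identifier begins with `"__"`
#' (`__no_feature`, `__ambiguous`, ...) are dropped. Malformed lines
#' and duplicated gene identifiers are errors.
#'
#' @param path file path.
#' @param parameter which transcriptome parameter the file measures:
#'   `"TR"`, `"RA"` or `"TA"`.
#' @param replicate positive integer replicate number.
#' @return data.frame with columns `gene_id`, `count`, `parameter`,
#'   `replicate`.
#' @examples
#' f <- tempfile()
#' writeLines(c("G1\t10", "__no_feature\t5"), f)
#' readCounts(f, "RA", 1)
#' @export
readCounts <- function(path, parameter = c("TR", "RA", "TA"),
                       replicate = 1L) {
    parameter <- match.arg(parameter)
    replicate <- as.integer(replicate)
    stopifnot(replicate >= 1L)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(gene_id = character(0), count = integer(0),
                          parameter = character(0), replicate = integer(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad))
        stop("malformed count line ", bad[1], " in ", path,
             ": expected gene_id<TAB>count")
    ids <- vapply(parts, `[[`, "", 1L)
    cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
    if (length(bad))
        stop("malformed count line ", bad[1], " in ", path,
             ": count must be a non-negative integer")
    keep <- !startsWith(ids, "__")
    ids <- ids[keep]
    cnt <- cnt[keep]
    if (anyDuplicated(ids))
        stop("duplicated gene id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    data.frame(gene_id = ids, count = as.integer(cnt),
               parameter = parameter, replicate = replicate)
}

#' Write a two-column count file
#'
#' Inverse of [readCounts()] (summary rows are not reproduced).
#'
#' @param counts data.frame with `gene_id` and `count`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path) {
    writeLines(paste(counts$gene_id, counts$count, sep = "\t"), path)
    invisible(path)
}

#' Read a gene-length table
#'
#' Two-column tab-separated table `gene_id<TAB>exon_length` (bases,
#' union of exons), with or without a header line.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `exon_length`.
#' @export
readGeneLengths <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expected two columns in ", path)
    if (is.na(suppressWarnings(as.numeric(df[1, 2]))))
        df <- df[-1, , drop = FALSE]  # first row is a header
    out <- data.frame(gene_id = as.character(df[[1]]),
                      exon_length = as.numeric(df[[2]]))
    if (any(!is.finite(out$exon_length)) || any(out$exon_length < 1))
        stop("exon_length must be >= 1")
    if (anyDuplicated(out$gene_id)) stop("duplicated gene id in ", path)
    out
}

#' Convert counts to RPKM
#'
#' `RPKM = count / (exon_length/1000) / (total/1e6)`: reads per
#' kilobase of exon model per million mapped reads. By default the
#' library size is the sum of the per-gene exon counts in the table
#' itself; an externally determined total-mapped-read count can be
#' supplied instead.
#'
#' @param counts data.frame from [readCounts()] (columns `gene_id`,
#'   `count`).
#' @param lengths data.frame with `gene_id` and `exon_length`; every
#'   counted gene must be present.
#' @param totalReads optional externally supplied mapped-read total;
#'   default `sum(counts$count)`.
#' @return named numeric vector of RPKM values.
#' @examples
#' cts <- data.frame(gene_id = "G1", count = 1000L)
#' len <- data.frame(gene_id = "G1", exon_length = 1000L)
#' rpkm(cts, len, totalReads = 1e6)  # 1000
#' @export
rpkm <- function(counts, lengths, totalReads = NULL) {
    miss <- setdiff(counts$gene_id, lengths$gene_id)
    if (length(miss))
        stop("genes missing from the length table: ",
             paste(head(miss, 10), collapse = ", "),
             if (length(miss) > 10) sprintf(" (and %d more)",
                                            length(miss) - 10) else "")
    total <- if (is.null(totalReads)) sum(counts$count) else totalReads
    if (total <= 0) stop("total mapped reads must be > 0")
    len <- lengths$exon_length[match(counts$gene_id, lengths$gene_id)]
    setNames(counts$count / (len / 1000) / (total / 1e6), counts$gene_id)
}

#' Assemble a TriadExperiment from count tables
#'
#' Converts each count table to RPKM and builds the container. All
#' tables must cover the same gene set (the intersection is used, with
#' a message when genes are dropped). Replicates are pooled into the
#' canonical per-parameter profile either by averaging replicate RPKMs
#' (`"mean"`, default) or by summing counts before the RPKM transform
#' (`"sum_counts"`).
#'
#' @param countTables list of data.frames from [readCounts()], together
#'   covering the three parameters.
#' @param lengths gene-length data.frame (see [readGeneLengths()]).
#' @param poolMethod `"mean"` or `"sum_counts"`.
#' @param totalReads optional named list of externally supplied library
#'   sizes, keyed `"<parameter>_rep<k>"`.
#' @return a [TriadExperiment-class].
#' @export
triadFromCounts <- function(countTables, lengths,
                            poolMethod = c("mean", "sum_counts"),
                            totalReads = NULL) {
    poolMethod <- match.arg(poolMethod)
    genes <- Reduce(intersect, lapply(countTables, `[[`, "gene_id"))
    nAll <- length(unique(unlist(lapply(countTables, `[[`, "gene_id"))))
    if (length(genes) < nAll)
        message(nAll - length(genes),
                " gene(s) absent from some samples dropped")
    if (!length(genes)) stop("no genes shared across all count tables")
    key <- vapply(countTables, function(ct)
        paste0(ct$parameter[1], "_rep", ct$replicate[1]), "")
    if (anyDuplicated(key)) stop("duplicated (parameter, replicate) table")
    reps <- list()
    sumCounts <- list()
    for (i in seq_along(countTables)) {
        ct <- countTables[[i]]
        ct <- ct[match(genes, ct$gene_id), ]
        p <- ct$parameter[1]
        v <- rpkm(ct, lengths, totalReads = totalReads[[key[i]]])
        reps[[p]] <- cbind(reps[[p]], v)
        sumCounts[[p]] <- if (is.null(sumCounts[[p]])) ct$count
                          else sumCounts[[p]] + ct$count
    }
    if (!all(.PARAMETERS %in% names(reps)))
        stop("count tables must cover TR, RA and TA")
    canon <- lapply(.PARAMETERS, function(p) {
        if (poolMethod == "mean") rowMeans(reps[[p]])
        else rpkm(data.frame(gene_id = genes, count = sumCounts[[p]]),
                  lengths)
    })
    names(canon) <- .PARAMETERS
    TriadExperiment(tr = canon$TR, ra = canon$RA, ta = canon$TA,
                    geneId = genes, replicates = reps,
                    poolMethod = poolMethod)
}

#' Read/write an RPKM matrix
#'
#' Tab-separated matrix with a `gene_id` column plus one column per
#' sample, named `TR`, `RA`, `TA` for canonical profiles and
#' `TR_rep1`, ... for replicates — the dialect written by
#' [writeRpkmMatrix()], for users entering the pipeline with
#' precomputed RPKM values.
#'
#' @param path file path.
#' @return `readRpkmMatrix`: a [TriadExperiment-class].
#' @export
readRpkmMatrix <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if (!"gene_id" %in% colnames(df)) stop("missing gene_id column")
    geneId <- as.character(df$gene_id)
    canon <- list()
    repsList <- list()
    for (cn in setdiff(colnames(df), "gene_id")) {
        m <- regmatches(cn, regexec("^(TR|RA|TA)(_rep([0-9]+))?$", cn))[[1]]
        if (!length(m)) stop("unrecognized column name: ", cn)
        p <- m[2]
        if (m[4] == "") canon[[p]] <- as.numeric(df[[cn]])
        else repsList[[p]] <- cbind(repsList[[p]], as.numeric(df[[cn]]))
    }
    TriadExperiment(tr = canon$TR, ra = canon$RA, ta = canon$TA,
                    geneId = geneId,
                    replicates = if (length(repsList)) repsList else NULL)
}

#' @param x a [TriadExperiment-class].
#' @return `writeRpkmMatrix`: `path`, invisibly.
#' @rdname readRpkmMatrix
#' @export
writeRpkmMatrix <- function(x, path) {
    a <- SummarizedExperiment::assay(x)
    df <- data.frame(gene_id = rownames(x), a, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
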