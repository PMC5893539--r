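#' Construct a UtrAnnotation
#'
#' @param geneId character gene ids.
#' @param utr5,utr3 UTR lengths in bases (>= 0).
#' @param cds CDS length in bases (> 0).
#' @return a [UtrAnnotation-class]; `mrna` and `proportion` are derived.
#' @examples
#' UtrAnnotation("G1", utr5 = 200, cds = 1000, utr3 = 800)  # proportion 0.5
#' @export
UtrAnnotation <- function(geneId, utr5, utr3, cds) {
    mrna <- utr5 + cds + utr3
    methods::new("UtrAnnotation", geneId = as.character(geneId),
                 utr5 = as.numeric(utr5), utr3 = as.numeric(utr3),
                 cds = as.numeric(cds), mrna = as.numeric(mrna),
                 proportion = (utr5 + utr3) / mrna)
}

setMethod("show", "UtrAnnotation", function(object) {
    cat("UtrAnnotation for", length(object@geneId), "genes\n")
    cat(sprintf("  UTR proportion: mean %.3f, median %.3f\n",
                mean(object@proportion), median(object@proportion)))
})

#' @rdname as.data.frame-methods
#' @export
setMethod("as.data.frame", "UtrAnnotation",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene_id = x@geneId, utr5_len = x@utr5, cds_len = x@cds,
               utr3_len = x@utr3, mrna_len = x@mrna,
               utr_proportion = x@proportion)
})

#' Read a precomputed UTR-length table
#'
#' Tab-separated table with header columns `gene_id`, `utr5_len`,
#' `cds_len`, `utr3_len`.
#'
#' @param path file path.
#' @return a [UtrAnnotation-class].
#' @export
readUtrTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "utr5_len", "cds_len", "utr3_len")
    if (!all(need %in% colnames(df)))
        stop("expected columns: ", paste(need, collapse = ", "))
    if (any(df$utr5_len < 0 | df$utr3_len < 0 | df$cds_len <= 0))
        stop("negative UTR length or non-positive CDS length")
    UtrAnnotation(df$gene_id, utr5 = df$utr5_len, utr3 = df$utr3_len,
                  cds = df$cds_len)
}

#' Derive UTR lengths from a GTF annotation
#'
#' Computes per-gene 5' UTR, CDS and 3' UTR lengths from the `exon` and
#' `CDS` features of a GTF file (1-based inclusive coordinates). For a
#' transcript, the CDS length is the number of exonic bases overlapping
#' the CDS span, the 5' UTR the exonic bases upstream of the first
#' coding base in transcript orientation, and the 3' UTR the exonic
#' bases downstream (strand respected). When a gene has several
#' transcripts, the representative is the one with the longest CDS,
#' ties broken by longest mRNA and then by lexicographic transcript id.
#' Transcripts without CDS features are skipped (with a warning when a
#' gene loses all its transcripts).
#'
#' @param path GTF file path.
#' @return a [UtrAnnotation-class].
#' @export
annotateUtrFromGtf <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type %in% c("exon", "CDS")]
    if (!length(gr)) stop("no exon/CDS features in ", path)
    txid <- gr$transcript_id
    gene <- gr$gene_id
    strand <- as.character(GenomicRanges::strand(gr))
    isCds <- gr$type == "CDS"
    st <- GenomicRanges::start(gr)
    en <- GenomicRanges::end(gr)
    res <- list()
    skippedGenes <- character(0)
    for (g in unique(gene)) {
        gi <- which(gene == g)
        best <- NULL
        for (tx in sort(unique(txid[gi]))) {
            ti <- gi[txid[gi] == tx]
            ex <- IRanges::reduce(IRanges::IRanges(st[ti][!isCds[ti]],
                                                   en[ti][!isCds[ti]]))
            cds <- ti[isCds[ti]]
            if (!length(cds) || !length(ex)) next
            cdsLo <- min(st[cds]); cdsHi <- max(en[cds])
            mrna <- sum(IRanges::width(ex))
            left <- sum(IRanges::width(IRanges::restrict(
                ex, end = cdsLo - 1L)))
            right <- sum(IRanges::width(IRanges::restrict(
                ex, start = cdsHi + 1L)))
            cdsLen <- mrna - left - right
            if (cdsLen <= 0) next
            neg <- strand[ti[1]] == "-"
            cand <- list(tx = tx, utr5 = if (neg) right else left,
                         utr3 = if (neg) left else right,
                         cds = cdsLen, mrna = mrna)
            if (is.null(best) || cand$cds > best$cds ||
                (cand$cds == best$cds && cand$mrna > best$mrna))
                best <- cand
        }
        if (is.null(best)) skippedGenes <- c(skippedGenes, g)
        else res[[g]] <- best
    }
    if (length(skippedGenes))
        warning("gene(s) without a usable CDS transcript skipped: ",
                paste(head(skippedGenes, 5), collapse = ", "))
    if (!length(res)) stop("no annotatable genes in ", path)
    UtrAnnotation(names(res),
                  utr5 = vapply(res, `[[`, 0, "utr5"),
                  utr3 = vapply(res, `[[`, 0, "utr3"),
                  cds = vapply(res, `[[`, 0, "cds"))
}

#' UTR-stratified index association
#'
#' Splits genes into UTR-proportion bins and computes the Pearson
#' correlation and OLS slope (stability on translation) within each
#' bin, tracing how the stabilization-by-translation coupling changes
#' with the share of the mRNA occupied by UTRs. Bins below the
#' occupancy floor are dropped.
#'
#' @param table an [IndexTable-class].
#' @param utr a [UtrAnnotation-class].
#' @param binEdges increasing bin edges over [0, 1]; default width 0.1.
#' @param minOccupancy minimum genes per reported bin, default 50.
#' @return data.frame with `bin_center`, `pearson_r`,
#'   `regression_slope`, `n_genes`, plus attribute `argmax_bin` (the
#'   bin centre with the largest correlation).
#' @export
utrBinnedAssociation <- function(table, utr, binEdges = seq(0, 1, by = 0.1),
                                 minOccupancy = 50L) {
    stopifnot(is(table, "IndexTable"), is(utr, "UtrAnnotation"))
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly increasing")
    i <- match(table@geneId, utr@geneId)
    ok <- !is.na(i)
    u <- utr@proportion[i[ok]]
    s <- table@stability[ok]
    tr <- table@translation[ok]
    bin <- cut(u, breaks = binEdges, include.lowest = TRUE, right = FALSE)
    rows <- lapply(seq_len(nlevels(bin)), function(b) {
        sel <- which(as.integer(bin) == b)
        if (length(sel) < minOccupancy) return(NULL)
        if (sd(s[sel]) == 0 || sd(tr[sel]) == 0) return(NULL)
        data.frame(bin_center = (binEdges[b] + binEdges[b + 1]) / 2,
                   pearson_r = cor(s[sel], tr[sel]),
                   regression_slope = .olsSlope(s[sel], tr[sel]),
                   n_genes = length(sel))
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows))
        stop("all UTR bins below the minimum occupancy of ", minOccupancy)
    out <- do.call(rbind, rows)
    attr(out, "argmax_bin") <- out$bin_center[which.max(out$pearson_r)]
    out
}

#' Select defier genes
#'
#' Rectangular selection of mRNAs with high stability index but low
#' translation index (stable yet poorly translated; the closed
#' rectangle includes its boundary). The defaults — stability index
#' >= 0 and translation index <= -1, i.e. TA below half of RA — are
#' documented conventions, not published thresholds.
#'
#' @param table an [IndexTable-class].
#' @param stabilityMin lower stability-index threshold (inclusive).
#' @param translationMax upper translation-index threshold (inclusive).
#' @return a [DefierSelection-class].
#' @export
selectDefiers <- function(table, stabilityMin = 0, translationMax = -1) {
    stopifnot(is.finite(stabilityMin), is.finite(translationMax))
    sel <- table@stability >= stabilityMin &
           table@translation <= translationMax
    if (!any(sel)) warning("defier selection is empty")
    methods::new("DefierSelection", stabilityMin = stabilityMin,
                 translationMax = translationMax,
                 geneIds = table@geneId[sel])
}

setMethod("show", "DefierSelection", function(object) {
    cat(sprintf(
        "DefierSelection: %d genes (stability >= %g, translation <= %g)\n",
        length(object@geneIds), object@stabilityMin, object@translationMax))
})

#' UTR-proportion shift of a gene selection
#'
#' Compares the UTR-proportion distribution of a selected gene set
#' (typically the defiers of [selectDefiers()]) against the background
#' of all annotated genes: shared-bin histograms and a two-sample
#' t-test of the proportions (Student pooled-variance by default).
#'
#' @param selection a [DefierSelection-class] or character gene ids.
#' @param utr a [UtrAnnotation-class]; also defines the background.
#' @param binWidth histogram bin width on the proportion scale.
#' @param welch use the Welch test instead of the pooled-variance test.
#' @return list with `histogram` (data.frame: `bin_mid`, `selection`,
#'   `background`), `p_value`, `mean_selection`, `mean_background`,
#'   `n_selection`, `n_background`.
#' @export
utrShiftTest <- function(selection, utr, binWidth = 0.1, welch = FALSE) {
    ids <- if (is(selection, "DefierSelection")) selection@geneIds
           else as.character(selection)
    sel <- utr@proportion[utr@geneId %in% ids]
    if (length(sel) < 3L)
        stop("need at least 3 annotated genes in the selection")
    bg <- utr@proportion
    breaks <- seq(0, 1, by = binWidth)
    if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
    hs <- hist(sel, breaks = breaks, plot = FALSE)
    hb <- hist(bg, breaks = breaks, plot = FALSE)
    tt <- t.test(sel, bg, var.equal = !welch)
    list(histogram = data.frame(bin_mid = hs$mids, selection = hs$counts,
                                background = hb$counts),
         p_value = tt$p.value,
         mean_selection = mean(sel), mean_background = mean(bg),
         n_selection = length(sel), n_background = length(bg))
}

#' UTR-proportion statistics of gene groups
#'
#' Mean and median UTR proportion per named gene group, plus pairwise
#' two-sample t-tests between groups (Student pooled-variance by
#' default, Welch on request). Gene ids absent from the annotation are
#' reported and excluded.
#'
#' @param geneSets named list of character gene-id vectors; each group
#'   needs >= 2 annotated genes.
#' @param utr a [UtrAnnotation-class].
#' @param welch use the Welch test.
#' @return list with `summary` (data.frame: `group`, `n`, `mean`,
#'   `median`), `tests` (data.frame: `group1`, `group2`, `t`,
#'   `p_value`) and `unknown` (excluded ids).
#' @export
groupUtrSummary <- function(geneSets, utr, welch = FALSE) {
    stopifnot(is.list(geneSets), !is.null(names(geneSets)))
    unknown <- character(0)
    vals <- lapply(geneSets, function(ids) {
        i <- match(ids, utr@geneId)
        unknown <<- c(unknown, ids[is.na(i)])
        utr@proportion[i[!is.na(i)]]
    })
    short <- names(vals)[vapply(vals, length, 1L) < 2L]
    if (length(short))
        stop("group(s) with fewer than 2 annotated genes: ",
             paste(short, collapse = ", "))
    if (length(unknown))
        message(length(unknown), " unknown gene id(s) excluded: ",
                paste(head(unknown, 5), collapse = ", "))
    summary <- data.frame(
        group = names(vals),
        n = vapply(vals, length, 1L),
        mean = vapply(vals, mean, 1),
        median = vapply(vals, median, 1),
        row.names = NULL)
    combos <- if (length(vals) >= 2) utils::combn(names(vals), 2) else NULL
    tests <- if (!is.null(combos)) {
        do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
            g1 <- combos[1, k]; g2 <- combos[2, k]
            tt <- tryCatch(
                t.test(vals[[g1]], vals[[g2]], var.equal = !welch),
                error = function(e) {
                    # degenerate zero-variance comparison
                    d <- mean(vals[[g1]]) - mean(vals[[g2]])
                    list(statistic = if (d == 0) 0 else sign(d) * Inf,
                         p.value = as.numeric(d == 0))
                })
            data.frame(group1 = g1, group2 = g2,
                       t = unname(tt$statistic), p_value = tt$p.value)
        }))
    } else data.frame(group1 = character(0), group2 = character(0),
                      t = numeric(0), p_value = numeric(0))
    list(summary = summary, tests = tests, unknown = unknown)
}
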