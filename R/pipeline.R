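#' Run the full coordination analysis
#'
#' Orchestrates the pipeline: data entry (synthetic generation, count
#' tables, or a precomputed RPKM matrix) -> expressed-gene filter ->
#' replicate consistency -> pairwise regression panel with the
#' two-slope test -> indices -> permutation null -> standardization
#' experiment -> dispersion summary -> UTR analyses -> similarity
#' strata. Every stage writes its table under `outDir`, and a manifest
#' JSON records the configuration hash, seed, per-stage gene counts and
#' the headline statistics.
#'
#' @param config configuration as a named list, or the path of a YAML
#'   file with the same structure. Recognized entries:
#'   \describe{
#'     \item{synthetic}{list of [syntheticTruth()] arguments; when
#'       present the dataset is generated.}
#'     \item{counts}{list of lists (`path`, `parameter`, `replicate`)
#'       of HTSeq-count files; requires `lengths` (path).}
#'     \item{rpkm_matrix}{path of a precomputed RPKM matrix.}
#'     \item{utr_table / gtf}{UTR annotation source (optional).}
#'     \item{pair_scores}{named list of pair-score TSV paths, keyed by
#'       source (optional).}
#'     \item{gene_sets}{named list of gene-id files, one id per line
#'       (optional).}
#'     \item{cutoff, min_params, n_reps, seed, shared_permutation,
#'       pseudocount, correlation_method, bin_edges, min_occupancy,
#'       stability_min, translation_max, score_bins, n_background,
#'       pool_method}{
#'       stage parameters with the package defaults.}
#'   }
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly (also written to
#'   `file.path(outDir, "manifest.json")`).
#' @export
runTriadPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed %||% 1L)
    manifest <- list(config_hash = .configHash(config), seed = seed,
                     stages = list(), headline = list(), skipped = list())
    out <- function(f) file.path(outDir, f)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    sim <- NULL
    utr <- NULL
    pairTables <- list()
    # -- data entry ----------------------------------------------------
    profile <- stage("data", {
        if (!is.null(config$synthetic)) {
            args <- config$synthetic
            args$seed <- args$seed %||% seed
            sim <- generateTriad(do.call(syntheticTruth, args))
            utr <- sim@utr
            pairTables <- sim@pairs
            sim@experiment
        } else if (!is.null(config$counts)) {
            lengths <- readGeneLengths(config$lengths)
            tables <- lapply(config$counts, function(cc)
                readCounts(cc$path, cc$parameter, cc$replicate %||% 1L))
            triadFromCounts(tables, lengths,
                            poolMethod = config$pool_method %||% "mean")
        } else if (!is.null(config$rpkm_matrix)) {
            readRpkmMatrix(config$rpkm_matrix)
        } else stop("no input: provide synthetic, counts or rpkm_matrix")
    })
    manifest$stages$data <- list(genes = nrow(profile))

    # -- filter --------------------------------------------------------
    filtered <- stage("filter", filterExpressed(
        profile, cutoff = config$cutoff %||% 1,
        minParams = config$min_params %||% 1L))
    fr <- S4Vectors::metadata(filtered)$filter
    jsonlite::write_json(fr, out("filter_report.json"), auto_unbox = TRUE)
    writeRpkmMatrix(filtered, out("rpkm_matrix.tsv"))
    manifest$stages$filter <- fr

    # -- replicate consistency ----------------------------------------
    repR2 <- tryCatch(replicateConsistency(filtered), error = function(e) {
        manifest$skipped$replicate_consistency <<- conditionMessage(e)
        NULL
    })
    if (!is.null(repR2))
        manifest$headline$replicate_r2 <- as.list(repR2)

    # -- regression panel ---------------------------------------------
    fits <- stage("regression", suppressWarnings(pairwisePanel(filtered)))
    fitJson <- lapply(fits, function(f) list(
        slope = f@slope, intercept = f@intercept, se = f@slopeSE,
        df = f@df, r_squared = f@rSquared, n = f@n,
        ci975 = as.list(slopeCI(f))))
    if (!is.null(fits[["RA2~RA1"]])) {
        cmpTA <- compareSlopes(fits[["RA2~RA1"]], fits[["TA~RA"]])
        fitJson$slope_comparison_TA_vs_replicate <- list(
            t_score = cmpTA@tScore, log10_p = cmpTA@log10P,
            ci_overlap = cmpTA@overlap)
        manifest$headline$slope_comparison <- list(
            t_score = cmpTA@tScore, log10_p = cmpTA@log10P)
    } else manifest$skipped$slope_comparison <- "fewer than 2 RA replicates"
    jsonlite::write_json(fitJson, out("fits.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$headline$slopes <- lapply(fits, function(f) f@slope)

    # -- indices -------------------------------------------------------
    tab <- stage("indices", computeIndices(
        filtered, pseudocount = config$pseudocount %||% 0))
    write.table(as.data.frame(tab), out("index_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    assoc <- indexAssociation(
        tab, method = config$correlation_method %||% "pearson")
    manifest$stages$indices <- list(genes = assoc$n)
    manifest$headline$index_r <- assoc$r
    manifest$headline$index_slope <- assoc$slope

    # -- permutation null ---------------------------------------------
    perm <- stage("permutation", permutationNull(
        filtered, nReps = config$n_reps %||% 1000L, seed = seed,
        shared = isTRUE(config$shared_permutation)))
    write.table(data.frame(rep = seq_len(perm@nReps),
                           correlation = perm@correlations,
                           slope = perm@slopes),
                out("permutation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    permSummary <- list(
        n_reps = perm@nReps, seed = perm@seed,
        observed_correlation = perm@observedCorrelation,
        observed_slope = perm@observedSlope,
        null_mean = mean(perm@correlations),
        null_max = max(perm@correlations),
        n_positive = sum(perm@correlations > 0),
        analytic_expectation = permutationNullExpectation(filtered))
    jsonlite::write_json(permSummary, out("permutation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$headline$permutation <- permSummary[c(
        "observed_correlation", "null_mean", "null_max", "n_positive")]

    # -- standardization experiment -----------------------------------
    std <- stage("standardization", standardizeProfiles(filtered))
    stdAssoc <- indexAssociation(computeIndices(std))
    manifest$headline$index_r_standardized <- stdAssoc$r

    # -- dispersion ----------------------------------------------------
    disp <- stage("dispersion", dispersionSummary(filtered))
    write.table(disp, out("dispersion.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$headline$dispersion_sd <- setNames(
        as.list(disp$sd), disp$parameter)

    # -- UTR analyses --------------------------------------------------
    if (is.null(utr)) {
        if (!is.null(config$utr_table)) utr <- readUtrTable(config$utr_table)
        else if (!is.null(config$gtf)) utr <- annotateUtrFromGtf(config$gtf)
    }
    if (is.null(utr)) {
        manifest$skipped$utr <- "no UTR annotation supplied"
    } else {
        curve <- stage("utr", utrBinnedAssociation(
            tab, utr,
            binEdges = config$bin_edges %||% seq(0, 1, by = 0.1),
            minOccupancy = config$min_occupancy %||% 50L))
        write.table(curve, out("utr_bin_curve.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        manifest$headline$utr_argmax_bin <- attr(curve, "argmax_bin")
        sel <- selectDefiers(
            tab, stabilityMin = config$stability_min %||% 0,
            translationMax = config$translation_max %||% -1)
        writeLines(sel@geneIds, out("defier_genes.txt"))
        manifest$stages$defiers <- list(selected = length(sel@geneIds))
        if (length(sel@geneIds) >= 3L) {
            shift <- utrShiftTest(sel, utr)
            jsonlite::write_json(
                shift[c("p_value", "mean_selection", "mean_background",
                        "n_selection", "n_background")],
                out("defier_utr_shift.json"), auto_unbox = TRUE,
                digits = NA)
            manifest$headline$defier_utr_shift_p <- shift$p_value
        }
        if (!is.null(config$gene_sets)) {
            sets <- lapply(config$gene_sets, readLines)
            gsum <- groupUtrSummary(sets, utr)
            jsonlite::write_json(list(summary = gsum$summary,
                                      tests = gsum$tests),
                                 out("group_utr_summary.json"),
                                 auto_unbox = TRUE, digits = NA)
        }
    }

    # -- similarity strata --------------------------------------------
    if (!is.null(config$pair_scores))
        for (src in names(config$pair_scores))
            pairTables[[src]] <- readPairScores(config$pair_scores[[src]],
                                                source = src)
    if (!length(pairTables)) {
        manifest$skipped$similarity_strata <- "no pair scores supplied"
    } else {
        strataOut <- list()
        for (src in names(pairTables)) {
            strata <- stage("strata", stratifyDistances(
                tab, pairTables[[src]],
                scoreBins = config$score_bins %||% c(0.25, 0.5, 0.75, 1),
                nBackground = config$n_background %||% 1e6,
                seed = seed))
            res <- stratumShiftTest(strata)
            write.table(res, out(paste0("strata_", src, ".tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            strataOut[[src]] <- res
        }
        manifest$headline$strata_medians <- lapply(strataOut, function(r)
            setNames(as.list(r$median), r$stratum))
    }

    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                force = TRUE), f)
    unname(tools::md5sum(f))
}
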