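test_that("UTR proportion arithmetic and invariants", {
    ann <- UtrAnnotation(c("a", "b"), utr5 = c(200, 0), utr3 = c(800, 0),
                         cds = c(1000, 900))
    expect_equal(ann@proportion, c(0.5, 0))
    expect_equal(ann@mrna, c(2000, 900))
    # scale invariance
    ann3 <- UtrAnnotation("a", utr5 = 600, utr3 = 2400, cds = 3000)
    expect_equal(ann3@proportion, 0.5)
    expect_error(UtrAnnotation("a", utr5 = -1, utr3 = 0, cds = 10),
                 "UTR lengths")
    expect_error(UtrAnnotation("a", utr5 = 1, utr3 = 0, cds = 0), "CDS")
})

test_that("GTF annotation computes exonic UTR/CDS lengths by strand", {
    gtf <- tempfile(fileext = ".gtf")
    writeLines(c(
        paste0("chr1\tsrc\texon\t1\t100\t.\t+\t.\t",
               "gene_id \"g1\"; transcript_id \"t1\";"),
        paste0("chr1\tsrc\texon\t201\t300\t.\t+\t.\t",
               "gene_id \"g1\"; transcript_id \"t1\";"),
        paste0("chr1\tsrc\tCDS\t51\t250\t.\t+\t.\t",
               "gene_id \"g1\"; transcript_id \"t1\";"),
        # same structure on the minus strand swaps the UTR sides
        paste0("chr2\tsrc\texon\t1\t100\t.\t-\t.\t",
               "gene_id \"g2\"; transcript_id \"t2\";"),
        paste0("chr2\tsrc\texon\t201\t300\t.\t-\t.\t",
               "gene_id \"g2\"; transcript_id \"t2\";"),
        paste0("chr2\tsrc\tCDS\t51\t230\t.\t-\t.\t",
               "gene_id \"g2\"; transcript_id \"t2\";"),
        # two transcripts: the longer CDS wins
        paste0("chr3\tsrc\texon\t1\t1000\t.\t+\t.\t",
               "gene_id \"g3\"; transcript_id \"t3a\";"),
        paste0("chr3\tsrc\tCDS\t101\t400\t.\t+\t.\t",
               "gene_id \"g3\"; transcript_id \"t3a\";"),
        paste0("chr3\tsrc\texon\t1\t1000\t.\t+\t.\t",
               "gene_id \"g3\"; transcript_id \"t3b\";"),
        paste0("chr3\tsrc\tCDS\t101\t800\t.\t+\t.\t",
               "gene_id \"g3\"; transcript_id \"t3b\";")), gtf)
    ann <- annotateUtrFromGtf(gtf)
    df <- as.data.frame(ann)
    g1 <- df[df$gene_id == "g1", ]
    # hand interval arithmetic: exonic bases 200; CDS spans 51..250,
    # exonic intersection 50 + 50 = 100; 50 bases on each side
    expect_equal(g1$utr5_len, 50)
    expect_equal(g1$cds_len, 100)
    expect_equal(g1$utr3_len, 50)
    expect_equal(g1$utr_proportion, 0.5)
    g2 <- df[df$gene_id == "g2", ]
    expect_equal(g2$utr5_len, 70)   # minus strand: downstream side is 5'
    expect_equal(g2$utr3_len, 50)
    g3 <- df[df$gene_id == "g3", ]
    expect_equal(g3$cds_len, 700)   # longest-CDS transcript chosen
})

test_that("a UTR table round-trips through the TSV reader", {
    ann <- UtrAnnotation(c("a", "b"), utr5 = c(10, 0), utr3 = c(30, 5),
                         cds = c(60, 95))
    f <- tempfile()
    write.table(as.data.frame(ann), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    back <- readUtrTable(f)
    expect_equal(back@proportion, ann@proportion)
})

test_that("single-bin UTR association reproduces the global association", {
    sim <- generateTriad(syntheticTruth(nGenes = 2000L, seed = 9L))
    tab <- computeIndices(filterExpressed(sim@experiment))
    cv <- utrBinnedAssociation(tab, sim@utr, binEdges = c(0, 1),
                               minOccupancy = 10L)
    keep <- tab@geneId %in% sim@utr@geneId
    global <- indexAssociation(new("IndexTable",
        geneId = tab@geneId[keep], stability = tab@stability[keep],
        translation = tab@translation[keep]))
    expect_equal(cv$pearson_r, global$r, tolerance = 1e-12)
    expect_equal(cv$regression_slope, global$slope, tolerance = 1e-12)
    expect_error(utrBinnedAssociation(tab, sim@utr, minOccupancy = 1e6),
                 "occupancy")
})

test_that("UTR-dependent coupling yields a decreasing bin curve", {
    sim <- generateTriad(syntheticTruth(nGenes = 8000L, seed = 41L))
    tab <- computeIndices(filterExpressed(sim@experiment))
    cv <- utrBinnedAssociation(tab, sim@utr)
    expect_lt(cor(cv$bin_center, cv$pearson_r, method = "spearman"), 0)
    expect_lt(cor(cv$bin_center, cv$regression_slope,
                  method = "spearman"), 0)
})

test_that("selectDefiers is a closed, monotone rectangle", {
    tab <- new("IndexTable", geneId = c("a", "b", "c"),
               stability = c(0, 1, -0.5), translation = c(-1, -2, -3))
    sel <- selectDefiers(tab, stabilityMin = 0, translationMax = -1)
    expect_setequal(sel@geneIds, c("a", "b"))  # boundary gene included
    all3 <- selectDefiers(tab, stabilityMin = -1e6, translationMax = 1e6)
    expect_setequal(all3@geneIds, c("a", "b", "c"))
    # relaxing a threshold never removes a gene
    relaxed <- selectDefiers(tab, stabilityMin = -1, translationMax = -1)
    expect_true(all(sel@geneIds %in% relaxed@geneIds))
    expect_warning(selectDefiers(tab, 100, -100), "empty")
})

test_that("planted defiers are recovered by the default rectangle", {
    sim <- generateTriad(syntheticTruth(nGenes = 8000L, seed = 19L))
    tab <- computeIndices(filterExpressed(sim@experiment))
    sel <- selectDefiers(tab)
    planted <- sim@latent$gene_id[sim@latent$defier]
    expect_gte(mean(planted %in% sel@geneIds), 0.9)
})

test_that("utrShiftTest detects the UTR shift of planted defiers", {
    sim <- generateTriad(syntheticTruth(nGenes = 6000L, seed = 27L))
    tab <- computeIndices(filterExpressed(sim@experiment))
    sh <- utrShiftTest(selectDefiers(tab), sim@utr)
    expect_lt(sh$p_value, 0.01)
    expect_gt(sh$mean_selection, sh$mean_background)
    # counts conserve group sizes
    expect_equal(sum(sh$histogram$selection), sh$n_selection)
    expect_equal(sum(sh$histogram$background), sh$n_background)
    # selection == background: identical histograms, p ~ 1
    all_sh <- utrShiftTest(sim@utr@geneId, sim@utr)
    expect_equal(all_sh$histogram$selection, all_sh$histogram$background)
    expect_gt(all_sh$p_value, 0.99)
    expect_error(utrShiftTest(sim@utr@geneId[1:2], sim@utr), "at least 3")
})

test_that("groupUtrSummary matches the pooled-variance t-test formula", {
    ann <- UtrAnnotation(sprintf("g%d", 1:6),
                         utr5 = c(2, 3, 4, 6, 7, 8) * 10,
                         utr3 = rep(0, 6),
                         cds = c(8, 7, 6, 4, 3, 2) * 10)
    res <- groupUtrSummary(list(lo = c("g1", "g2", "g3"),
                                hi = c("g4", "g5", "g6")), ann)
    expect_equal(res$summary$mean, c(0.3, 0.7))
    expect_equal(res$summary$median, c(0.3, 0.7))
    # brute-force pooled-variance two-sample t
    a <- c(0.2, 0.3, 0.4); b <- c(0.6, 0.7, 0.8)
    sp2 <- (2 * var(a) + 2 * var(b)) / 4
    tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    pHand <- 2 * pt(-abs(tHand), df = 4)
    expect_equal(res$tests$t, tHand, tolerance = 1e-12)
    expect_equal(res$tests$p_value, pHand, tolerance = 1e-12)

    same <- groupUtrSummary(list(x = c("g1", "g2"), y = c("g1", "g2")), ann)
    expect_equal(same$tests$p_value, 1)
    expect_error(groupUtrSummary(list(x = "g1", y = c("g2", "g3")), ann),
                 "fewer than 2")
    res2 <- suppressMessages(groupUtrSummary(
        list(x = c("g1", "g2", "nope"), y = c("g3", "g4")), ann))
    expect_equal(res2$unknown, "nope")
})

test_that("identical proportions give mean == median", {
    ann <- UtrAnnotation(c("a", "b"), utr5 = c(30, 30), utr3 = c(0, 0),
                         cds = c(70, 70))
    res <- groupUtrSummary(list(g = c("a", "b"), h = c("a", "b")), ann)
    expect_equal(res$summary$mean, c(0.3, 0.3))
    expect_equal(res$summary$median, c(0.3, 0.3))
})
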