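test_that("fold change is the raw-scale ratio of group means", {
    prot <- workedExampleMeans("protein")
    hc <- prot[prot$contrast == "hc_vs_pre", ]
    se <- meansToToyTable(hc)
    fc <- foldChange(se, "ref", "cmp")
    expect_equal(round(unname(fc["APO(a)", "fc"]), 3), 2.197)
    expect_equal(round(unname(fc["GPX3", "fc"]), 3), 0.704)
    # identical groups give fc exactly 1
    same <- OmicsTable(matrix(c(5, 5, 5, 5), 1), c("g1", "g1", "g2",
        "g2"))
    expect_equal(foldChange(same, "g1", "g2")$fc, 1)
    # zero reference mean is flagged, not an error
    z <- OmicsTable(rbind(f1 = c(0, 0, 3, 3)), rep(c("r", "c"),
        each = 2))
    fz <- foldChange(z, "r", "c")
    expect_true(is.na(fz$fc) && fz$flagged)
})

test_that("fold change is scale-equivariant", {
    se <- sampleOmicsTable(30, 5, planted = 1:3, trueFC = 1.8,
        seed = 61)
    fc1 <- foldChange(se, "A", "B")$fc
    se2 <- se
    SummarizedExperiment::assay(se2, "intensity") <-
        SummarizedExperiment::assay(se, "intensity") * 1e3
    expect_equal(foldChange(se2, "A", "B")$fc, fc1)
})

test_that("group tests cover Welch, paired and rank-sum variants", {
    same <- OmicsTable(rbind(f = c(1, 2, 3, 1, 2, 3)),
        rep(c("a", "b"), each = 3))
    expect_equal(unname(groupTest(same, "a", "b")), 1)

    se <- sampleOmicsTable(20, 8, planted = 1:10, trueFC = 1.5,
        paired = TRUE, sigmaSubject = 1, seed = 62)
    pPair <- groupTest(se, "A", "B", paired = TRUE,
        logTransform = TRUE)
    pUnp <- groupTest(se, "A", "B", paired = FALSE,
        logTransform = TRUE)
    # strong shared subject effect: pairing must help on planted rows
    expect_lt(median(pPair[1:10]), median(pUnp[1:10]))

    pRank <- groupTest(se, "A", "B", method = "ranksum")
    expect_true(all(pRank >= 0 & pRank <= 1))

    tiny <- OmicsTable(rbind(f = c(1, 2, 3)), c("a", "a", "b"))
    expect_error(groupTest(tiny, "a", "b"), "at least 2")
})

test_that("paired tests demand a subject bijection", {
    m <- rbind(f1 = 1:6, f2 = 6:1)
    se <- OmicsTable(m, rep(c("pre", "post"), each = 3),
        subject = c("s1", "s2", "s3", "s1", "s2", "s4"))
    expect_error(groupTest(se, "pre", "post", paired = TRUE), "s3")
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(c(1, 1)), c(1, 1))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    for (seed in 1:50) {
        p <- withr::with_seed(seed, runif(sample(1:50, 1))^2)
        expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
    }
})

test_that("screening verdicts combine FC, p and VIP gates", {
    dr <- data.frame(
        fc = c(2.197, 1.05, 0.70, 0.80, 1.5),
        p = c(0.014, 0.001, 0.20, 0.01, 0.03),
        vip = c(3.104, 2, 2, 0.5, 1.2))
    out <- screenFeatures(dr)
    expect_equal(out$verdict, c("up", "ns", "ns", "ns", "up"))
    expect_equal(unname(attr(out, "summary")),
        c(2L, 0L, 3L))
    # without a vip column only FC and p gate
    out2 <- screenFeatures(dr[, c("fc", "p")])
    expect_equal(out2$verdict[4], "down")
    # FDR mode gates on q
    dr$q <- c(0.04, 0.5, 0.5, 0.5, 0.2)
    out3 <- screenFeatures(dr, useFdr = TRUE)
    expect_equal(out3$verdict, c("up", "ns", "ns", "ns", "ns"))
    expect_error(screenFeatures(dr[, c("fc", "p")], useFdr = TRUE),
        "'q'")
})

test_that("null tables keep the raw positive rate near alpha", {
    se <- sampleOmicsTable(400, 10, planted = integer(), seed = 63)
    dr <- differentialScreen(se, "A", "B")
    pRate <- mean(dr$p < 0.05)
    expect_lt(abs(pRate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
    expect_lt(mean(dr$q < 0.05), 0.01)
    expect_gt(mean(dr$verdict == "ns"), 0.9)
})

test_that("planted effects are enriched among 'up' verdicts", {
    se <- sampleOmicsTable(200, 10, planted = 1:20, trueFC = 1.7,
        seed = 64)
    dr <- differentialScreen(se, "A", "B", withVip = TRUE)
    recall <- mean(dr$verdict[1:20] == "up")
    fpr <- mean(dr$verdict[-(1:20)] == "up")
    expect_gt(recall, 0.5)
    expect_lt(fpr, recall)
})

test_that("omics tables read from TSV with a sample sheet", {
    se <- sampleOmicsTable(10, 4, planted = 1, trueFC = 3, seed = 65)
    tab <- withr::local_tempfile(fileext = ".tsv")
    des <- withr::local_tempfile(fileext = ".tsv")
    x <- SummarizedExperiment::assay(se, "intensity")
    write.table(data.frame(feature = rownames(x), x), tab, sep = "\t",
        quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = colnames(x),
        group = SummarizedExperiment::colData(se)$group), des,
        sep = "\t", quote = FALSE, row.names = FALSE)
    back <- readOmicsTable(tab, des)
    expect_equal(SummarizedExperiment::assay(back, "intensity"), x)
    expect_equal(SummarizedExperiment::colData(back)$group,
        SummarizedExperiment::colData(se)$group)
})
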