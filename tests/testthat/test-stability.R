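test_that("cohort splits partition patients and harmonize columns", {
    coh <- samplePlantedModules(200, c(3, 3), seed = 31)
    yrs <- withr::with_seed(32, sample(1993:2024, 200, replace = TRUE))
    SummarizedExperiment::colData(coh)$discharge_year <- yrs
    halves <- splitCohort(coh, "discharge_year", 2014)
    expect_equal(ncol(halves$A) + ncol(halves$B), 200L)
    expect_true(all(patientData(halves$A)$discharge_year <= 2014))
    expect_true(all(patientData(halves$B)$discharge_year > 2014))

    SummarizedExperiment::colData(coh)$discharge_year <- 2000L
    expect_error(splitCohort(coh, "discharge_year", 2014), "empty")
})

test_that("columns degenerate in one subset are dropped from both", {
    m <- rbind(A = c(1L, 0L, 1L, 0L, 1L, 0L),
               B = c(1L, 1L, 0L, 0L, 1L, 0L),
               C = c(1L, 1L, 0L, 0L, 0L, 0L))  # absent in late era
    colnames(m) <- paste0("p", 1:6)
    coh <- ComorbidityCohort(m,
        covariates = data.frame(
            discharge_year = c(2000L, 2001L, 2002L, 2020L, 2021L,
                2022L)))
    expect_message(halves <- splitCohort(coh, "discharge_year", 2014),
        "degenerate")
    expect_equal(halves$dropped, "C")
    expect_setequal(rownames(halves$A), c("A", "B"))
    expect_setequal(rownames(halves$B), c("A", "B"))
})

test_that("Fisher-z interval reproduces the published worked example", {
    ci <- fisherZCI(0.7179, 78)
    expect_equal(unname(round(ci, 4)), c(0.5896, 0.8109))
    ci0 <- fisherZCI(0, 103)
    expect_equal(unname(ci0), c(-tanh(1.96 / 10), tanh(1.96 / 10)),
        tolerance = 1e-3)
    expect_error(fisherZCI(0.5, 3), "n < 4")
})

test_that("Fisher-z intervals shrink with n and are z-symmetric", {
    widths <- vapply(c(10, 50, 200, 1000),
        function(n) diff(fisherZCI(0.6, n)), numeric(1))
    expect_true(all(diff(widths) < 0))
    ci <- fisherZCI(0.37, 40)
    expect_equal(atanh(ci[["upper"]]) - atanh(0.37),
        atanh(0.37) - atanh(ci[["lower"]]), tolerance = 1e-12)
})

test_that("comparing a network with itself gives perfect agreement", {
    cm <- randomCouplingMatrix(8, seed = 41, maskProb = 0.1)
    cmp <- compareNetworks(cm, cm)
    expect_equal(cmp$edge_r, 1)
    expect_equal(cmp$strength_r, 1)
    expect_equal(cmp$rank_consistency, 1)
    expect_equal(cmp$kendall_tau, 1)
    expect_true(cmp$edge_ci[1] <= 1 && cmp$edge_ci[2] <= 1)

    small <- randomCouplingMatrix(3, seed = 42, maskProb = 0)
    expect_error(compareNetworks(small, small), "fewer than 4")
    other <- randomCouplingMatrix(8, seed = 43)
    cm2 <- makeCouplingMatrix(couplingStrengths(other),
        codes = letters[1:8])
    expect_error(compareNetworks(cm, cm2), "node set")
})

test_that("paired-edge counting uses pairs unmasked in both subsets", {
    J <- couplingStrengths(randomCouplingMatrix(5, seed = 45,
        maskProb = 0))
    maskA <- matrix(FALSE, 5, 5)
    maskA[1, 2] <- maskA[2, 1] <- TRUE
    maskB <- matrix(FALSE, 5, 5)
    maskB[3, 4] <- maskB[4, 3] <- TRUE
    cmp <- compareNetworks(makeCouplingMatrix(J, maskA),
        makeCouplingMatrix(J, maskB))
    expect_equal(cmp$n_edges, 10L - 2L)
})

test_that("subset agreement grows with per-half sample size", {
    edgeR <- vapply(c(250, 1000, 4000), function(n) {
        coh <- samplePlantedModules(2 * n, c(4, 3), nNoise = 3,
            activationProb = 0.3, baselineProb = 0.08,
            boostProb = 0.5, seed = 51)
        SummarizedExperiment::colData(coh)$half <-
            rep(c(1L, 2L), n)
        halves <- suppressMessages(splitCohort(coh, "half", 1L))
        cmp <- compareNetworks(
            couplingMatrix(estimateProbabilities(halves$A)),
            couplingMatrix(estimateProbabilities(halves$B)))
        cmp$edge_r
    }, numeric(1))
    expect_true(all(diff(edgeR) > 0))
})

test_that("baseline tables report chi-square/V and Welch/d with bands", {
    mA <- rbind(X = c(rep(1L, 30), rep(0L, 70)),
                Y = c(rep(1L, 50), rep(0L, 50)))
    colnames(mA) <- paste0("a", 1:100)
    mB <- rbind(X = c(rep(1L, 70), rep(0L, 30)),
                Y = c(rep(1L, 50), rep(0L, 50)))
    colnames(mB) <- paste0("b", 1:100)
    cohA <- ComorbidityCohort(mA,
        covariates = data.frame(age = rnorm(100, 40, 10),
            flat = rep(1.5, 100)))
    cohB <- ComorbidityCohort(mB,
        covariates = data.frame(age = rnorm(100, 40, 10),
            flat = rep(1.5, 100)))
    out <- baselineComparison(cohA, cohB, c("X", "Y", "age", "flat"))
    # 2x2 table [[30,70],[70,30]]: chi2 = 32 on n = 200, V = 0.4
    expect_equal(out$statistic[out$variable == "X"], 32)
    expect_equal(out$effect[out$variable == "X"], 0.4)
    expect_equal(out$band[out$variable == "X"], "moderate")
    expect_equal(out$effect[out$variable == "Y"], 0)
    expect_equal(out$band[out$variable == "flat"], "zero-variance")
    expect_true(is.na(out$p[out$variable == "flat"]))
    withBH <- baselineComparison(cohA, cohB, c("X", "Y"),
        adjust = "BH")
    expect_true("q" %in% names(withBH))
})

test_that("identical continuous distributions give d = 0", {
    v <- rnorm(50)
    cohA <- ComorbidityCohort(rbind(A = rep(0:1, 25), B = rep(1:0, 25)),
        covariates = data.frame(age = v))
    cohB <- ComorbidityCohort(rbind(A = rep(0:1, 25), B = rep(1:0, 25)),
        covariates = data.frame(age = v))
    out <- baselineComparison(cohA, cohB, "age")
    expect_equal(out$effect, 0)
    expect_equal(out$band, "negligible")
})
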