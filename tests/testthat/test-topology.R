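test_that("network edges mirror unmasked coupling pairs", {
    J <- matrix(c(0, 0.5, 0.2, 0.5, 0, -0.4, 0.2, -0.4, 0), 3)
    mask <- matrix(FALSE, 3, 3)
    mask[1, 3] <- mask[3, 1] <- TRUE
    cm <- makeCouplingMatrix(J, mask)
    net <- buildNetwork(cm)
    expect_equal(length(igraph::E(net)), 2L)
    expect_equal(length(igraph::E(buildNetwork(cm, 10))), 0L)
    full <- buildNetwork(makeCouplingMatrix(J))
    expect_equal(length(igraph::E(full)), 3L)
})

test_that("path, triangle and star graphs match hand-derived centralities", {
    # path A-B-C, unit weights
    J <- matrix(0, 3, 3)
    J[1, 2] <- J[2, 1] <- 1
    J[2, 3] <- J[3, 2] <- 1
    ct <- centralities(buildNetwork(makeCouplingMatrix(J)))
    expect_equal(ct$betweenness, c(0, 1, 0))
    expect_equal(ct$strength, c(1, 2, 1))
    expect_equal(ct$closeness, c(2 / 3, 1, 2 / 3))

    # equal-weight triangle: no bridges
    Jt <- matrix(0.8, 3, 3); diag(Jt) <- 0
    expect_equal(
        centralities(buildNetwork(makeCouplingMatrix(Jt)))$betweenness,
        c(0, 0, 0))

    # star on 4 nodes, weights 2
    Js <- matrix(0, 4, 4)
    Js[1, 2:4] <- Js[2:4, 1] <- 2
    cts <- centralities(buildNetwork(makeCouplingMatrix(Js)))
    expect_equal(cts$strength, c(6, 2, 2, 2))
    expect_equal(cts$expectedInfluence, cts$strength)  # nonneg weights
})

test_that("negative edges count in strength/EI but not in paths", {
    J <- matrix(0, 3, 3)
    J[1, 2] <- J[2, 1] <- 0.5
    J[2, 3] <- J[3, 2] <- -0.5
    ct <- centralities(buildNetwork(makeCouplingMatrix(J)))
    expect_equal(ct$strength[2], 1)
    expect_equal(ct$expectedInfluence[2], 0)
    # C reachable only through the negative edge -> isolated for paths
    expect_equal(ct$closeness[3], 0)
    expect_equal(ct$betweenness, c(0, 0, 0))
    # two-step expected influence adds neighbour EI through edges
    ct2 <- centralities(buildNetwork(makeCouplingMatrix(J)),
        twoStep = TRUE)
    expect_equal(ct2$expectedInfluence2[1],
        ct2$expectedInfluence[1] + 0.5 * ct2$expectedInfluence[2])
})

test_that("centralities agree with exhaustive path enumeration", {
    for (seed in 1:25) {
        p <- withr::with_seed(seed, sample(3:7, 1))
        cm <- randomCouplingMatrix(p, seed = 1000 + seed)
        got <- as.data.frame(centralities(buildNetwork(cm)))
        want <- oracleCentralities(cm)
        expect_equal(got$strength, want$strength, tolerance = 1e-10)
        expect_equal(got$expectedInfluence, want$expectedInfluence,
            tolerance = 1e-10)
        expect_equal(got$betweenness, want$betweenness,
            tolerance = 1e-8)
        expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
    }
})

test_that("module detection keeps strict supra-threshold components", {
    J <- matrix(0, 5, 5,
        dimnames = list(LETTERS[1:5], LETTERS[1:5]))
    J["A", "B"] <- J["B", "A"] <- 0.6
    J["B", "C"] <- J["C", "B"] <- 0.6
    J["D", "E"] <- J["E", "D"] <- 0.7
    J["A", "C"] <- J["C", "A"] <- 0.1
    part <- detectModules(buildNetwork(makeCouplingMatrix(J)), 0.5)
    expect_equal(moduleClusters(part),
        list(c("A", "B", "C"), c("D", "E")))
    expect_equal(moduleSingletons(part), character())

    high <- detectModules(buildNetwork(makeCouplingMatrix(J)), 0.8)
    expect_equal(length(moduleClusters(high)), 0L)
    expect_setequal(moduleSingletons(high), LETTERS[1:5])

    # negative edges never pass a positive threshold
    Jn <- J; Jn["D", "E"] <- Jn["E", "D"] <- -0.9
    pn <- detectModules(buildNetwork(makeCouplingMatrix(Jn)), 0.5)
    expect_true(all(c("D", "E") %in% moduleSingletons(pn)))
})

test_that("module detection is node-order invariant and threshold-monotone", {
    for (seed in 1:10) {
        cm <- randomCouplingMatrix(6, seed = 500 + seed, maskProb = 0)
        net <- buildNetwork(cm)
        part1 <- detectModules(net, 0.4)
        perm <- withr::with_seed(seed, sample(6))
        J <- couplingStrengths(cm)[perm, perm]
        part2 <- detectModules(buildNetwork(makeCouplingMatrix(J)), 0.4)
        canon <- function(p) lapply(moduleClusters(p), sort)
        expect_setequal(canon(part1), canon(part2))

        # raising the threshold only refines, never merges
        lo <- detectModules(net, 0.3)
        hi <- detectModules(net, 0.9)
        for (cl in moduleClusters(hi)) {
            inside <- vapply(moduleClusters(lo),
                function(big) all(cl %in% big), logical(1))
            expect_true(any(inside))
        }
    }
})

test_that("tier rules use strict thresholds and the hub exclusion list", {
    ct <- S4Vectors::DataFrame(
        code = c("S23", "S27", "S44", "S86", "S15"),
        strength = c(12.3, 4.1, 1, 2, 10),
        expectedInfluence = 0, betweenness = c(5, 65, 5, 80, 60),
        closeness = c(0.02, 0.0125, 0.001, 0.01, 0.013))
    out <- classifyTiers(ct, exclude = "S86")
    expect_equal(out$tier,
        c("core", "hub", "peripheral", "peripheral", "peripheral"))
    # strength 10 and betweenness 60 do NOT exceed the cutoffs
    expect_equal(out$tier[5], "peripheral")
    expect_equal(out$highEfficiency, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("exports round-trip through GraphML and are deterministic", {
    cm <- randomCouplingMatrix(5, seed = 77, maskProb = 0)
    net <- buildNetwork(cm)
    ct <- classifyTiers(centralities(net))
    part <- detectModules(net, 0.4)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    exportNetwork(net, ct, part, d1)
    exportNetwork(net, ct, part, d2)
    back <- igraph::read_graph(file.path(d1, "network.graphml"),
        format = "graphml")
    expect_equal(sort(igraph::E(back)$weight),
        sort(igraph::E(net)$weight), tolerance = 1e-9)
    expect_true("cluster" %in% igraph::vertex_attr_names(back))
    expect_identical(readLines(file.path(d1, "modules.tsv")),
        readLines(file.path(d2, "modules.tsv")))

    # empty network still yields a valid file with 0 edges
    empty <- buildNetwork(cm, minAbsJ = 100)
    ct0 <- centralities(empty)
    exportNetwork(empty, ct0, detectModules(empty, 0.5), d2)
    e <- igraph::read_graph(file.path(d2, "network.graphml"),
        format = "graphml")
    expect_equal(length(igraph::E(e)), 0L)
})

test_that("planted modules are recovered end to end", {
    coh <- samplePlantedModules(5000, c(3, 3), seed = 9)
    cm <- couplingMatrix(estimateProbabilities(coh))
    part <- detectModules(buildNetwork(cm), 0.5)
    expect_equal(moduleClusters(part),
        list(c("M1_1", "M1_2", "M1_3"), c("M2_1", "M2_2", "M2_3")))
})
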