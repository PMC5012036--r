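## The mid-run 6-node state of the worked example (after the (L1,L2) and
## (L6,L7) joins), reconstructed from the Hamming matrix by replaying the
## documented joins; used for deterministic detection tests.
workedExampleState <- function() {
    D <- hammingDistance(buildPresenceAbsence(exampleHybridDatabase()))
    njUpdate(njUpdate(D, "L1", "L2"), "L6", "L7")
}

test_that("the degree estimator is exact on convex constructions", {
    sim <- randomAdditiveMatrix(7, seed = 21)
    D <- injectHybrid(sim$D, "T02", "T05", 0.3, "H1")
    expect_equal(estimateAlpha(D, "H1", "T02", "T05"), 0.3,
                 tolerance = 1e-12)
    expect_lt(leastSquaresFit(D, "H1", "T02", "T05", 0.3), 1e-20)
    ## grid search confirms the closed form is the minimizer
    expect_equal(gridMinLS(D, "H1", "T02", "T05"), 0.3)
    ## swapping the donor roles flips the degree
    expect_equal(estimateAlpha(D, "H1", "T05", "T02"), 0.7,
                 tolerance = 1e-12)
})

test_that("a symmetric construction forces the midpoint degree", {
    sim <- randomAdditiveMatrix(7, seed = 22)
    D <- injectHybrid(sim$D, "T01", "T06", 0.5, "H1")
    expect_equal(estimateAlpha(D, "H1", "T01", "T06"), 0.5,
                 tolerance = 1e-12)
})

test_that("indistinguishable donors give NA, not an error", {
    D <- matrix(3, 5L, 5L, dimnames = list(letters[1:5], letters[1:5]))
    diag(D) <- 0
    ## every X_k is zero: i and j look identical from everywhere
    expect_true(is.na(estimateAlpha(D, "a", "b", "c")))
    expect_error(estimateAlpha(D[1:4, 1:4], "a", "b", "c"), "at least 5")
})

test_that("the misfit is positive away from the optimum and the grid
           minimizer matches the closed form on random matrices", {
    sim <- randomAdditiveMatrix(7, seed = 23)
    D <- injectHybrid(sim$D, "T03", "T07", 0.4, "H1")
    expect_gt(leastSquaresFit(D, "H1", "T03", "T07", 0.5), 0)
    for (r in 1:10) {
        M <- randomNoisyMatrix(6, seed = 300 + r)
        a <- estimateAlpha(M, "N01", "N03", "N05")
        expect_equal(gridMinLS(M, "N01", "N03", "N05",
                               seq(0, 1, by = 0.01)),
                     min(max(round(a * 100) / 100, 0), 1),
                     tolerance = 0.011)
        expect_lte(leastSquaresFit(M, "N01", "N03", "N05", a),
                   leastSquaresFit(M, "N01", "N03", "N05", a + 0.01))
    }
})

test_that("the reticulation score vanishes on additive quartets and
           tracks deviation linearly", {
    tr <- ape::read.tree(text = "((i:1.2,h:0.7):0.9,(j:1.1,k:0.4):0.3);")
    D <- stats::cophenetic(ape::unroot(tr))
    expect_equal(hybridizationScore(D, "h", "i", "j"), 0)
    ## pulling h off the tree by eps (for all k outside the triplet)
    eps <- 0.37
    D5 <- randomAdditiveMatrix(6, seed = 3)$D
    base <- hybridizationScore(D5, "T01", "T03", "T05")
    Dp <- D5
    ks <- setdiff(rownames(D5), c("T01", "T03", "T05"))
    Dp["T01", ks] <- Dp["T01", ks] + eps
    Dp[ks, "T01"] <- Dp[ks, "T01"] + eps
    expect_equal(hybridizationScore(Dp, "T01", "T03", "T05"), base + eps)
    ## mutually equidistant nodes
    De <- matrix(2, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
    diag(De) <- 0
    expect_equal(hybridizationScore(De, "a", "b", "c"), 0)
})

test_that("neighbor deviation is zero for true neighbors and matches the
           exhaustive scan elsewhere", {
    sim <- randomAdditiveMatrix(8, seed = 13)
    ## find a cherry of the generating tree
    tr <- sim$tree
    tips <- seq_along(tr$tip.label)
    anc <- tr$edge[match(tips, tr$edge[, 2L]), 1L]
    cherryAnc <- anc[duplicated(anc)][1L]
    pair <- sort(tr$tip.label[tips[anc == cherryAnc]])[1:2]
    nd <- neighborDeviation(sim$D, pair[1L], pair[2L])
    expect_true(all(abs(nd$deviations) < 1e-9))
    ## exhaustive scan agreement on random 5-taxon matrices
    for (r in 1:10) {
        M <- randomNoisyMatrix(5, seed = 400 + r)
        nd <- neighborDeviation(M, "N01", "N02")
        ora <- vapply(c("N03", "N04", "N05"),
                      function(h) oracleDelta(M, "N01", "N02", h), 0)
        expect_equal(nd$deviations, ora)
        expect_equal(unname(nd$h), names(which.max(abs(ora)))[1L])
    }
})

test_that("deviation respects matrix symmetries", {
    ## matrix invariant under swapping c and d
    D <- matrix(0, 5L, 5L, dimnames = list(letters[1:5], letters[1:5]))
    D["a", "b"] <- 1
    D["a", "c"] <- D["a", "d"] <- 2
    D["b", "c"] <- D["b", "d"] <- 3
    D["c", "d"] <- 1.5
    D["a", "e"] <- 4; D["b", "e"] <- 5
    D["c", "e"] <- D["d", "e"] <- 2.5
    D <- D + t(D)
    nd <- neighborDeviation(D, "a", "b")
    expect_equal(nd$deviations[["c"]], nd$deviations[["d"]])
})

test_that("detection accepts the worked-example hybrid and nothing under
           a prohibitive score threshold", {
    D6 <- workedExampleState()
    pair <- njSelectPair(D6)
    expect_equal(unname(pair), c("L1+L2", "L3"))
    cand <- detectAtStep(D6, pair[1L], pair[2L],
                         DetectionParameters(0, 0.1, 0.9))
    expect_equal(cand$h, "L4")
    expect_equal(sort(c(cand$donor1, cand$donor2)), c("L3", "L5"))
    expect_equal(cand$alpha, 0.5)
    expect_equal(cand$ls, 0)
    expect_lt(cand$ls, cand$delta^2)
    ## a minimum score above any attainable value degenerates to NJ
    expect_null(detectAtStep(D6, pair[1L], pair[2L],
                             DetectionParameters(1e9, 0.1, 0.9)))
})

test_that("detection recovers an injected hybrid with its degree", {
    sim <- simulateHybridMatrix(10, alpha = 0.3, seed = 1)
    net <- inferNetwork(sim$D, DetectionParameters(0, 0.1, 0.9))
    m <- lexinet:::.matchTruth(net, sim$recipient, sim$parent1,
                               sim$parent2)
    expect_true(m$recovered)
    expect_lt(abs(m$alphaHat - 0.3), 0.05)
})

test_that("additive matrices yield zero reticulations and the NJ tree", {
    sim <- randomAdditiveMatrix(9, seed = 41)
    net <- inferNetwork(sim$D, DetectionParameters(0, 0.1, 0.9))
    expect_equal(nrow(reticulations(net)), 0L)
    expect_equal(rfDist(backboneTree(net), njTree(sim$D)), 0)
})

test_that("an infinite score threshold reduces inference to plain NJ", {
    for (r in 1:50) {
        M <- randomNoisyMatrix(6, seed = 600 + r)
        net <- inferNetwork(M, DetectionParameters(Inf, 0.1, 0.9))
        expect_equal(nrow(reticulations(net)), 0L)
        expect_equal(rfDist(backboneTree(net), njTree(M)), 0)
    }
})

test_that("small matrices disable detection with a warning", {
    D <- randomAdditiveMatrix(4, seed = 2)$D
    expect_warning(net <- inferNetwork(D), "greater than four")
    expect_equal(nrow(reticulations(net)), 0L)
    expect_equal(sort(backboneTree(net)$tip.label), rownames(D))
    expect_error(inferNetwork(D[1:2, 1:2]), "at least 3")
})

test_that("reticulation degrees always sum to one exactly", {
    for (s in c(5, 9, 14)) {
        sim <- simulateHybridMatrix(12, seed = s)
        r <- reticulations(inferNetwork(sim$D,
                                        DetectionParameters(0, 0.1, 0.9)))
        if (nrow(r))
            expect_identical(r$degree1 + r$degree2, rep(1, nrow(r)))
    }
})

test_that("relaxing the score threshold never loses reticulations", {
    for (r in 1:8) {
        M <- randomNoisyMatrix(8, seed = 700 + r)
        counts <- vapply(c(2, 1, 0.5, 0.1, 0), function(ms)
            nrow(reticulations(inferNetwork(
                M, DetectionParameters(ms, 0.1, 0.9)))), 0L)
        expect_true(all(diff(counts) >= 0L))
    }
})

test_that("invalid detection parameters are rejected", {
    expect_error(DetectionParameters(0, 0.9, 0.1), "alphaMin")
    expect_error(DetectionParameters(0, 0, 0.9), "alphaMin")
    expect_error(DetectionParameters(0, 0.1, 1), "alphaMin")
})

test_that("iterated removal accumulates hybrids masked in the first run", {
    ## construction with two nested hybrids: HB between two clades, HA
    ## between HB and a third taxon; one of them only becomes detectable
    ## after the other is removed
    sim <- randomAdditiveMatrix(10, seed = 11)
    ed <- lexinet:::.leafEdgeDistances(sim$tree)
    labs <- rownames(sim$D)
    edm <- ed[labs, labs]
    cand <- which(upper.tri(edm) & edm >= 4, arr.ind = TRUE)
    p1 <- labs[cand[1L, 1L]]; p2 <- labs[cand[1L, 2L]]
    DB <- injectHybrid(sim$D, p1, p2, 0.5, "HB")
    q <- setdiff(labs, c(p1, p2))[1L]
    DA <- injectHybrid(DB, "HB", q, 0.5, "HA")
    p <- DetectionParameters(0, 0.1, 0.9)
    single <- reticulations(inferNetwork(DA, p))
    iter <- reticulations(iterateRemoval(DA, p))
    expect_false("HA" %in% single$recipient)
    expect_true("HA" %in% iter$recipient)
    expect_gt(iter$round[iter$recipient == "HA"], 1L)
})

test_that("iterated removal equals a single run when nothing is found", {
    sim <- randomAdditiveMatrix(8, seed = 55)
    p <- DetectionParameters(0, 0.1, 0.9)
    single <- inferNetwork(sim$D, p)
    iter <- iterateRemoval(sim$D, p)
    expect_equal(nrow(reticulations(iter)), 0L)
    expect_equal(rfDist(backboneTree(iter), backboneTree(single)), 0)
    ## and maxRounds = 1 always equals a single run
    sim2 <- simulateHybridMatrix(10, alpha = 0.4, seed = 5)
    one <- iterateRemoval(sim2$D, p, maxRounds = 1L)
    ref <- inferNetwork(sim2$D, p)
    got <- reticulations(one)[, names(reticulations(ref))]
    rownames(got) <- NULL
    want <- reticulations(ref)
    rownames(want) <- NULL
    expect_equal(got, want)
})
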