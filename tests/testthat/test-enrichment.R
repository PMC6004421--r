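test_that("EASE penalization matches the hypergeometric oracle", {
    expect_equal(easeOra(0, 10, 50, 200), 1)
    expect_equal(easeOra(1, 10, 50, 200), 1)
    # penalized cell 7: sum of hypergeometric point masses from 7 up
    oracle <- sum(stats::dhyper(7:10, 50, 150, 10))
    expect_equal(easeOra(8, 10, 50, 200), oracle)
    expect_error(easeOra(11, 10, 50, 200), "inconsistent")
    expect_error(easeOra(5, 10, 4, 200), "inconsistent")
})

test_that("node ORA boundaries and determinism", {
    net <- PathwayNetwork("toy",
        nodes = list(A = c("g1", "g2"), B = "g3", C = c("g4", "g5")),
        edges = list(c("A", "B"), c("B", "C")))
    uni <- sprintf("g%d", 1:10)
    allFlag <- setNames(rep(TRUE, 10), uni)
    res <- nodeOra(net, allFlag, nTrials = 1000L, seed = 1L)
    expect_equal(res$score, 3)
    expect_equal(res$p, 1)
    noFlag <- setNames(rep(FALSE, 10), uni)
    res0 <- nodeOra(net, noFlag, nTrials = 1000L, seed = 1L)
    expect_equal(res0$score, 0)
    expect_equal(res0$p, 1)
    flags <- setNames(uni %in% c("g1", "g4", "g6", "g7"), uni)
    r1 <- nodeOra(net, flags, nTrials = 5000L, seed = 11L)
    r2 <- nodeOra(net, flags, nTrials = 5000L, seed = 11L)
    expect_identical(r1$p, r2$p)
    expect_error(nodeOra(net, flags[1:4]), "missing from the universe")
})

test_that("node ORA converges to the exhaustive permutation oracle", {
    net <- PathwayNetwork("toy",
        nodes = list(A = c("g1", "g2"), B = "g3", C = c("g4", "g5")),
        edges = list(c("A", "B"), c("B", "C")))
    uni <- sprintf("g%d", 1:10)
    flags <- setNames(uni %in% c("g1", "g4", "g6", "g7"), uni)
    obs <- 2L  # nodes A and C are hit
    # oracle: enumerate all C(10, 4) = 210 flag placements
    placements <- utils::combn(10L, 4L)
    members <- list(A = c(1L, 2L), B = 3L, C = c(4L, 5L))
    scores <- apply(placements, 2L, function(ix)
        sum(vapply(members, function(m) any(m %in% ix), logical(1L))))
    exact <- mean(scores >= obs)
    nT <- 200000L
    mc <- nodeOra(net, flags, nTrials = nT, seed = 3L)
    expect_equal(mc$score, obs)
    se <- sqrt(exact * (1 - exact) / nT)
    expect_lt(abs(mc$p - exact), 3 * se + 1 / nT)
})

test_that("preranked GSEA matches hand-computed running sums", {
    scores <- setNames(seq(10, 1), sprintf("g%d", 1:10))
    # single-member set at the list head: first step reaches 1
    expect_equal(gseaPreranked(scores, "g1", nPermutations = 10L)$ES, 1)
    # single member at position 2: run = (-1/9, -1/9 + 1)
    expect_equal(gseaPreranked(scores, "g2", nPermutations = 10L)$ES,
        8 / 9)
    # a top-k set maximizes ES among sets of its size
    esTop <- gseaPreranked(scores, c("g1", "g2", "g3"),
        nPermutations = 10L)$ES
    expect_gt(esTop, 0)
    for (i in 1:10) {
        set.seed(i)
        other <- sample(names(scores), 3L)
        expect_lte(gseaPreranked(scores, other,
            nPermutations = 10L)$ES, esTop + 1e-12)
    }
    # empty intersection is not testable
    expect_false(gseaPreranked(scores, "nope")$testable)
})

test_that("preranked GSEA agrees with the reference implementation", {
    skip_if_not_installed("fgsea")
    set.seed(12)
    stats <- sort(setNames(rexp(50), sprintf("g%d", 1:50)),
        decreasing = TRUE)
    for (i in 1:5) {
        set.seed(i)
        gs <- sample(names(stats), 8L)
        mine <- gseaPreranked(stats, gs, nPermutations = 10L)$ES
        ref <- fgsea::calcGseaStat(unname(stats),
            selectedStats = match(gs, names(stats)), gseaParam = 1)
        expect_equal(mine, ref, tolerance = 1e-12)
    }
})

test_that("GSEA null p-values are roughly uniform", {
    set.seed(13)
    pvals <- vapply(1:200, function(i) {
        scores <- setNames(sample(seq(0.1, 5, length.out = 40)),
            sprintf("g%d", 1:40))
        gseaPreranked(scores, sample(names(scores), 6L),
            nPermutations = 200L, seed = i)$p
    }, numeric(1L))
    # permutation p-values are discrete, so ignore the KS ties warning
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value,
        0.01)
})

test_that("Fisher node aggregation has its closed-form values", {
    net1 <- PathwayNetwork("one", nodes = list(A = "g1"))
    expect_equal(nodeGsaFisher(net1, c(g1 = 0.37)), 0.37)
    expect_equal(nodeGsaFisher(net1, c(g1 = 1)), 1)
    net2 <- PathwayNetwork("two", nodes = list(A = "g1", B = "g2"))
    stat <- -2 * (log(0.01) + log(0.04))
    expect_equal(stat, 15.65, tolerance = 1e-2)
    expect_equal(nodeGsaFisher(net2, c(g1 = 0.01, g2 = 0.04)),
        pchisq(stat, 4, lower.tail = FALSE))
    expect_equal(pchisq(stat, 4, lower.tail = FALSE), 0.0035,
        tolerance = 1e-2)
    expect_warning(nodeGsaFisher(net1, c(g1 = 0)), "clamped")
    # pooled single-stage alternative collapses node structure
    net3 <- PathwayNetwork("cmplx", nodes = list(A = c("g1", "g2")))
    expect_equal(nodeGsaFisher(net3, c(g1 = 0.2, g2 = 0.3),
        twoStage = FALSE),
        pchisq(-2 * (log(0.2) + log(0.3)), 4, lower.tail = FALSE))
})

test_that("BH adjustment matches the hand step-up computation", {
    expect_equal(bhFdr(0.02), 0.02)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(14)
    p <- runif(50)
    adj <- bhFdr(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_error(bhFdr(c(0.5, 0)), "")
})

test_that("the global null keeps the FDR-selected fraction near zero", {
    set.seed(15)
    nPath <- 2000L
    p <- runif(nPath)
    frac <- mean(bhFdr(p) < 0.01)
    expect_lte(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / nPath))
})
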