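test_that("simulation is byte-identical under a fixed seed", {
    cfg <- chainConfig(c(0.8, 0.5), n = 50L, seed = 99L,
        background = list(nGenes = 20L, fractionInflated = 0.5,
            inflationFactor = 2, targetGroup = "A"))
    s1 <- simulatePathwayExpression(cfg)
    s2 <- simulatePathwayExpression(cfg)
    expect_identical(assayOf(s1$data), assayOf(s2$data))
    b1 <- simulateBackgroundGenes(cfg)
    b2 <- simulateBackgroundGenes(cfg)
    expect_identical(assayOf(b1), assayOf(b2))
    expect_identical(SummarizedExperiment::rowData(b1)$inflated,
        SummarizedExperiment::rowData(b2)$inflated)
})

test_that("zero coefficients give identity covariance in the limit", {
    cfg <- chainConfig(c(0, 0), n = 20000L, seed = 5L)
    sim <- simulatePathwayExpression(cfg)
    S <- cov(t(assayOf(sim$data)[, 1:20000]))
    expect_lt(max(abs(S - diag(3))), 0.05)
    expect_equal(max(abs(sim$truth$impliedCovariance$A - diag(3))), 0)
})

test_that("chain covariance matches the closed form b1*b2*var(x)", {
    n <- 100000L
    cfg <- chainConfig(c(0.8, 0.5), n = n, seed = 17L)
    sim <- simulatePathwayExpression(cfg)
    m <- assayOf(sim$data)[, seq_len(n)]
    cxz <- cov(m["x", ], m["z", ])
    # MC standard error of a sample covariance of bivariate normals
    sxx <- 1; szz <- 1.41; sxz <- 0.4
    mcse <- sqrt((sxx * szz + sxz^2) / n)
    expect_lt(abs(cxz - 0.4), 3 * mcse)
    # the recorded truth matches the empirical covariance entrywise
    S <- cov(t(m))
    tr <- sim$truth$impliedCovariance$A
    bound <- 3 * sqrt((diag(tr) %o% diag(tr) + tr^2) / n)
    expect_true(all(abs(S - tr[rownames(S), colnames(S)]) < bound))
})

test_that("covariate effects are shared across groups and recoverable", {
    net <- chainNetwork(c("x", "y"))
    eff <- matrix(c(0.5, -0.4), nrow = 2, ncol = 1,
        dimnames = list(c("x", "y"), "PC1"))
    cfg <- simulationConfig(net,
        coefficients = list(A = c("x->y" = 0.5), B = c("x->y" = 0.5)),
        covariateEffects = eff, nPerGroup = c(A = 2000L, B = 2000L),
        seed = 3L)
    sim <- simulatePathwayExpression(cfg)
    # one shared effect matrix by construction
    expect_identical(sim$truth$covariateEffects["x", "PC1"], 0.5)
    cd <- SummarizedExperiment::colData(sim$data)
    m <- assayOf(sim$data)
    for (g in c("A", "B")) {
        ix <- cd$group == g
        b <- coef(lm(m["x", ix] ~ cd$PC1[ix]))[2L]
        expect_lt(abs(b - 0.5), 0.1)
    }
})

test_that("background nulls split 50/50 and inflated genes separate", {
    net <- chainNetwork(c("x", "y"))
    mk <- function(frac, fact, n) simulationConfig(net,
        coefficients = list(A = c("x->y" = 0), B = c("x->y" = 0)),
        nPerGroup = c(A = n, B = n),
        background = list(nGenes = 1000L, fractionInflated = frac,
            inflationFactor = fact, targetGroup = "A"), seed = 21L)
    nullBg <- simulateBackgroundGenes(mk(0, 1, 200L))
    gv <- groupVariances(nullBg, case = "A", control = "B")
    frac <- mean(gv$caseGreater, na.rm = TRUE)
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
    # inflated genes: one-sided Levene rejects at high rate
    inflBg <- simulateBackgroundGenes(mk(1, 4, 200L))
    m <- assayOf(inflBg)
    grp <- SummarizedExperiment::colData(inflBg)$group
    p <- leveneOneSided(m[, grp == "A"], m[, grp == "B"])
    expect_gt(mean(p < 0.05), 0.9)
})

test_that("background genes are mutually uncorrelated", {
    net <- chainNetwork(c("x", "y"))
    cfg <- simulationConfig(net,
        coefficients = list(A = c("x->y" = 0), B = c("x->y" = 0)),
        nPerGroup = c(A = 150L, B = 150L),
        background = list(nGenes = 60L, fractionInflated = 0,
            inflationFactor = 1, targetGroup = "A"), seed = 8L)
    bg <- simulateBackgroundGenes(cfg)
    r <- cor(t(assayOf(bg)))
    off <- abs(r[upper.tri(r)])
    expect_lt(mean(off), 3 / sqrt(300))
})

test_that("invalid configurations are rejected with clear errors", {
    net <- chainNetwork(c("x", "y"))
    expect_error(simulationConfig(net,
        coefficients = list(A = c("x->q" = 1), B = c("x->y" = 1)),
        nPerGroup = c(A = 10L, B = 10L)), "not in the network")
    expect_error(simulationConfig(net,
        coefficients = list(A = c("x->y" = 1), B = c("x->y" = 1)),
        errorVariances = c(x = -1), nPerGroup = c(A = 10L, B = 10L)),
        "positive")
    expect_error(simulationConfig(net,
        coefficients = list(A = c("x->y" = 1), B = c("x->y" = 1)),
        nPerGroup = c(A = 2L, B = 10L)), "n >= 3")
    expect_error(simulationConfig(net,
        coefficients = list(A = c("x->y" = 1), B = c("x->y" = 1)),
        nPerGroup = c(A = 10L, B = 10L),
        background = list(nGenes = 5L, fractionInflated = 0.5,
            inflationFactor = 0.5, targetGroup = "A")), ">= 1")
})

test_that("a cyclic system with unit feedback has no reduced form", {
    net <- PathwayNetwork("cyc", nodes = list(x = "x", y = "y"),
        edges = list(c("x", "y"), c("y", "x")))
    cfg <- simulationConfig(net,
        coefficients = list(A = c("x->y" = 1, "y->x" = 1),
            B = c("x->y" = 1, "y->x" = 1)),
        nPerGroup = c(A = 10L, B = 10L))
    expect_error(simulatePathwayExpression(cfg), "singular")
})
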