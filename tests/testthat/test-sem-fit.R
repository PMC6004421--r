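test_that("the ML discrepancy has its closed-form values and properties", {
    S <- matrix(c(2, 1, 1, 2), 2)
    expect_equal(mlDiscrepancy(S, S), 0)
    # ln|I| + tr(S) - ln|S| - p = 0 + 4 - ln 3 - 2
    expect_equal(mlDiscrepancy(S, diag(2)), 2 - log(3))
    expect_error(mlDiscrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
        "positive definite")
    # nonnegativity over random PD pairs (KL-type divergence)
    set.seed(42)
    for (i in 1:100) {
        p <- sample(2:5, 1L)
        A <- matrix(rnorm(p * p), p)
        B <- matrix(rnorm(p * p), p)
        expect_gte(mlDiscrepancy(crossprod(A) + diag(p),
            crossprod(B) + diag(p)), 0)
    }
})

test_that("a saturated model fits any covariance exactly", {
    set.seed(1)
    rd <- randomDagConfig(4L, 11L, n = 300L)
    sim <- simulatePathwayExpression(rd$config)
    Y <- assayOf(sim$data)[, 1:300]
    fit <- fitSem(saturatedModel(rownames(Y)), Y)
    expect_true(fit@converged)
    expect_lt(abs(fit@Fml), 1e-8)
    idx <- suppressWarnings(fitIndices(fit))
    expect_equal(idx$df, 0)
    expect_equal(idx$cfi, 1)
    expect_equal(idx$rmsea, 0)
})

test_that("parameters and their uncertainties are recovered from truth", {
    rd <- randomDagConfig(4L, 23L, n = 5000L)
    sim <- simulatePathwayExpression(rd$config)
    model <- semFromNetwork(enumerateAlternatives(rd$network)[[1L]])
    fit <- fitSem(model, assayOf(sim$data)[, 1:5000])
    expect_true(fit@converged)
    expect_true(checkIdentifiability(fit))
    co <- rd$config@coefficients$A
    for (k in names(co)) {
        sd_ <- strsplit(k, "->")[[1L]]
        lab <- paste0(sd_[2L], "~", sd_[1L])
        expect_lt(abs(fit@estimates[lab] - co[[k]]), 4 * fit@se[lab])
    }
})

test_that("degenerate inputs are flagged, not raised", {
    set.seed(2)
    Y <- matrix(rnorm(300), 3, 100,
        dimnames = list(c("x", "y", "z"), NULL))
    Y["z", ] <- 1  # constant observed variable
    fit <- fitSem(semModel(rbind(c("x", "y"), c("y", "z"))), Y)
    expect_false(checkIdentifiability(fit))
    expect_match(paste(attr(checkIdentifiability(fit), "diagnostics"),
        collapse = " "), "positive definite")
    # perfectly collinear pair
    Y2 <- matrix(rnorm(200), 2, 100, dimnames = list(c("x", "y"), NULL))
    Y2 <- rbind(Y2, z = Y2["y", ] * 2)
    fit2 <- fitSem(semModel(rbind(c("x", "y"), c("y", "z"))), Y2)
    expect_false(checkIdentifiability(fit2))
    # duplicated free path: two parameters for one edge
    set.seed(3)
    Y3 <- matrix(rnorm(400), 2, 200, dimnames = list(c("x", "y"), NULL))
    dup <- semModel(rbind(c("x", "y"), c("x", "y")))
    fit3 <- fitSem(dup, Y3)
    expect_false(checkIdentifiability(fit3))
})

test_that("n <= p is a validation error", {
    Y <- matrix(rnorm(9), 3, 3, dimnames = list(c("x", "y", "z"), NULL))
    expect_error(fitSem(semModel(rbind(c("x", "y"), c("y", "z"))), Y),
        "must exceed")
})

test_that("estimates are invariant to sample and variable order", {
    rd <- randomDagConfig(4L, 5L, n = 800L)
    sim <- simulatePathwayExpression(rd$config)
    Y <- assayOf(sim$data)[, 1:800]
    model <- semFromNetwork(enumerateAlternatives(rd$network)[[1L]])
    f1 <- fitSem(model, Y)
    set.seed(9)
    f2 <- fitSem(model, Y[, sample(ncol(Y))])
    expect_equal(f1@estimates, f2@estimates, tolerance = 1e-6)
    f3 <- fitSem(model, Y[rev(rownames(Y)), ])
    expect_equal(f1@estimates, f3@estimates, tolerance = 1e-6)
})

test_that("multigroup with no constraints equals per-group fits", {
    cfg <- chainConfig(c(0.8, 0.5), c(0.2, 0.5), n = 300L, seed = 13L)
    sim <- simulatePathwayExpression(cfg)
    gr <- splitByGroup(sim$data)
    model <- semFromNetwork(enumerateAlternatives(
        chainNetwork())[[1L]])
    mg <- fitMultigroup(model, gr)
    for (g in c("A", "B")) {
        single <- fitSem(model, gr[[g]])
        expect_equal(mg@fits[[g]]@estimates, single@estimates,
            tolerance = 1e-6)
    }
    expect_equal(mg@chisq,
        sum(vapply(c("A", "B"), function(g)
            (ncol(gr[[g]]) - 1) * fitSem(model, gr[[g]])@Fml,
            numeric(1L))), tolerance = 1e-6)
})

test_that("fully constrained multigroup reduces to the pooled fit", {
    # identical data in both groups: the equality-constrained optimum is
    # exactly the single-group optimum on that data
    rd <- randomDagConfig(4L, 19L, n = 400L)
    sim <- simulatePathwayExpression(rd$config)
    Y <- assayOf(sim$data)[, 1:400]
    model <- semFromNetwork(enumerateAlternatives(rd$network)[[1L]])
    mg <- fitMultigroup(model, list(A = Y, B = Y), constraints = "all")
    single <- fitSem(model, Y)
    expect_equal(mg@fits$A@estimates, single@estimates, tolerance = 1e-6)
    expect_identical(mg@fits$A@estimates, mg@fits$B@estimates)
    k <- nFreeParams(model)
    expect_equal(mg@df, 2 * 4 * 5 / 2 - k)
})

test_that("Wald difference tests have the stated arithmetic and symmetry", {
    cfg <- chainConfig(c(0.9, 0.5), c(0.3, 0.5), n = 400L, seed = 29L)
    sim <- simulatePathwayExpression(cfg)
    gr <- splitByGroup(sim$data)
    model <- semFromNetwork(enumerateAlternatives(chainNetwork())[[1L]])
    mg <- fitMultigroup(model, gr)
    w <- waldDifferenceTest(mg, c("x", "y"))
    # the reported z is exactly (theta1 - theta2)/sqrt(se1^2 + se2^2)
    expect_equal(w$z,
        (w$estimates[1L] - w$estimates[2L]) / sqrt(sum(w$se^2)))
    expect_equal(w$p, 2 * pnorm(-abs(w$z)))
    # swapping group order flips the sign, not the p-value
    mgRev <- fitMultigroup(model, gr[c("B", "A")])
    wRev <- waldDifferenceTest(mgRev, c("x", "y"))
    expect_equal(wRev$z, -w$z, tolerance = 1e-5)
    expect_equal(wRev$p, w$p, tolerance = 1e-5)
    # hand case: 0.5 vs 0.1 with SE 0.1 each
    z <- (0.5 - 0.1) / sqrt(0.1^2 + 0.1^2)
    expect_equal(z, 2.8284, tolerance = 1e-4)
    expect_equal(2 * pnorm(-z), 0.0047, tolerance = 1e-2)
    expect_error(waldDifferenceTest(mg, c("z", "x")), "no free path")
})

test_that("fitting the independence baseline itself gives CFI = 0", {
    cfg <- chainConfig(c(0.9, 0.8), n = 1000L, seed = 37L)
    sim <- simulatePathwayExpression(cfg)
    Y <- assayOf(sim$data)[, 1:1000]
    indep <- semModel(variables = c("x", "y", "z"))
    fit <- fitSem(indep, Y)
    idx <- fitIndices(fit)
    expect_equal(idx$cfi, 0, tolerance = 1e-6)
    expect_equal(idx$chisq, (fit@n - 1) *
        (-as.numeric(determinant(cov2cor(fit@S), TRUE)$modulus)),
        tolerance = 1e-4)
})

test_that("a misspecified independence model on chain data blows up RMSEA", {
    nBad <- 0L
    for (r in 1:20) {
        cfgR <- chainConfig(c(0.9, 0.8, 0.7), n = 1000L,
            seed = 1000L + r, vars = c("x", "y", "z", "w"))
        simR <- simulatePathwayExpression(cfgR)
        Yr <- assayOf(simR$data)[, 1:1000]
        fitM <- fitSem(semModel(variables = rownames(Yr)), Yr)
        if (fitIndices(fitM)$rmsea > 0.2) nBad <- nBad + 1L
    }
    expect_gte(nBad, 19L)
})
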