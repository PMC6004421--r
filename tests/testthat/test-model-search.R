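test_that("star annotation uses strict thresholds", {
    expect_identical(starAnnotation(0.20), "ns")
    expect_identical(starAnnotation(0.05), "ns")
    expect_identical(starAnnotation(0.049), "*")
    expect_identical(starAnnotation(0.01), "*")
    expect_identical(starAnnotation(0.009), "**")
    expect_identical(starAnnotation(0.001), "**")
    expect_identical(starAnnotation(0.0005), "***")
    expect_identical(starAnnotation(c(1, 0, NA)), c("ns", "***", NA))
    expect_error(starAnnotation(1.2), "")
})

test_that("a single-alternative pathway selects its sole model", {
    sel <- selectionExperiment(101L, n = 400L)
    serineLike <- PathwayNetwork("solo",
        nodes = list(A = "g1", B = "g2", C = "g3", D = "g4", E = "g5"),
        edges = list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E")))
    rep_ <- searchBestModel(serineLike, splitByGroup(sel$data),
        control = "CTL")
    expect_equal(rep_$nGenerated, 1L)
    expect_equal(rep_$selectedIndex, 1L)
    expect_s4_class(rep_[["selected"]], "ResolvedNetwork")
    expect_true(all(rep_$wald$testable))
})

test_that("degenerate criteria produce a structured no-model result", {
    sel <- selectionExperiment(102L, n = 400L)
    rep_ <- searchBestModel(sel$network, splitByGroup(sel$data),
        criteria = searchCriteria(rmseaCeiling = 0), control = "CTL")
    expect_null(rep_[["selected"]])
    expect_equal(rep_$nSurviving, 0L)
    expect_true(all(nzchar(rep_$perAlternative$status)))
    expect_error(groupInformationComparison(rep_), "no admissible")
})

test_that("the search is deterministic and selects the max-CFI survivor", {
    sel <- selectionExperiment(103L, n = 600L)
    r1 <- searchBestModel(sel$network, splitByGroup(sel$data),
        control = "CTL")
    r2 <- searchBestModel(sel$network, splitByGroup(sel$data),
        control = "CTL")
    expect_identical(r1$selectedIndex, r2$selectedIndex)
    expect_identical(r1$wald, r2$wald)
    surv <- r1$perAlternative[r1$perAlternative$status == "surviving", ]
    expect_true(all(r1$indices$cfi >= surv$cfi - 1e-6))
})

test_that("the true generating alternative wins on matched data", {
    sel <- selectionExperiment(104L, n = 1000L)
    rep_ <- searchBestModel(sel$network, splitByGroup(sel$data),
        control = "CTL")
    expect_equal(rep_$selectedIndex, sel$truthIndex)
})

test_that("a planted path difference is flagged, null paths are not", {
    sel <- selectionExperiment(105L, n = 1000L, caseShift = 1.0)
    rep_ <- searchBestModel(sel$network, splitByGroup(sel$data),
        control = "CTL")
    expect_equal(rep_$selectedIndex, sel$truthIndex)
    w <- rep_$wald
    expect_lt(w$p[w$path == "g2~g1"], 0.05)
    expect_identical(w$stars[w$path == "g2~g1"], "***")
})

test_that("inflated-noise groups are penalized by AIC and BIC", {
    # same structure in both groups, but the case group is generated with
    # tripled structural error variances: its likelihood is lower, so its
    # information criteria should be higher in most replicates
    worse <- 0L
    nRep <- 30L
    for (r in seq_len(nRep)) {
        co <- c(0.7, 0.6)
        base <- chainConfig(co, co, n = 250L, seed = 5000L + r)
        infl <- chainConfig(co, co, n = 250L, seed = 6000L + r,
            errorVariances = c(x = 3, y = 3, z = 3))
        dCtl <- splitByGroup(simulatePathwayExpression(base)$data)$A
        dCase <- splitByGroup(simulatePathwayExpression(infl)$data)$A
        model <- semFromNetwork(enumerateAlternatives(
            chainNetwork())[[1L]])
        mg <- fitMultigroup(model, list(SCZ = dCase, CTL = dCtl))
        if (mg@aic[["SCZ"]] > mg@aic[["CTL"]] &&
            mg@bic[["SCZ"]] > mg@bic[["CTL"]]) worse <- worse + 1L
    }
    expect_gte(worse / nRep, 0.9)
})

test_that("group information comparison reports the better group", {
    sel <- selectionExperiment(106L, n = 500L)
    rep_ <- searchBestModel(sel$network, splitByGroup(sel$data),
        control = "CTL")
    gi <- groupInformationComparison(rep_)
    expect_identical(gi$bestByAic, names(which.min(gi$aic)))
    expect_identical(gi$bestByBic, names(which.min(gi$bic)))
    # equal n, equal parameter count: AIC and BIC orderings agree
    expect_identical(order(gi$aic), order(gi$bic))
})
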