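# Shared builders for synthetic networks, models and datasets.

chainNetwork <- function(vars = c("x", "y", "z")) {
    nodes <- as.list(vars)
    names(nodes) <- vars
    edges <- lapply(seq_len(length(vars) - 1L),
        function(i) c(vars[i], vars[i + 1L]))
    PathwayNetwork("chain", nodes = nodes, edges = edges)
}

chainConfig <- function(coefsA, coefsB = coefsA, n = 500L, seed = 1L,
                        vars = c("x", "y", "z"), ...) {
    net <- chainNetwork(vars)
    keys <- paste0(vars[-length(vars)], "->", vars[-1L])
    simulationConfig(net,
        coefficients = list(A = setNames(coefsA, keys),
            B = setNames(coefsB, keys)),
        nPerGroup = c(A = n, B = n), seed = seed, ...)
}

# Random acyclic structural model over nVars variables: each ordered pair
# (i < j) gets an edge with probability pEdge; coefficients U(-0.9, 0.9),
# error variances U(0.5, 1.5).
randomDagConfig <- function(nVars, seed, pEdge = 0.5, n = 1000L,
                            twoGroup = FALSE) {
    set.seed(seed)
    vars <- sprintf("v%02d", seq_len(nVars))
    edges <- list()
    for (i in seq_len(nVars - 1L))
        for (j in (i + 1L):nVars)
            if (runif(1) < pEdge)
                edges[[length(edges) + 1L]] <- c(vars[i], vars[j])
    if (!length(edges)) edges <- list(c(vars[1L], vars[2L]))
    nodes <- as.list(vars)
    names(nodes) <- vars
    net <- PathwayNetwork("rand", nodes = nodes, edges = edges)
    keys <- vapply(edges, function(e) paste0(e[1L], "->", e[2L]),
        character(1L))
    coA <- setNames(runif(length(keys), -0.9, 0.9), keys)
    coB <- if (twoGroup) setNames(runif(length(keys), -0.9, 0.9), keys)
        else coA
    ev <- setNames(runif(nVars, 0.5, 1.5), vars)
    list(network = net,
        config = simulationConfig(net,
            coefficients = list(A = coA, B = coB), errorVariances = ev,
            nPerGroup = c(A = n, B = n), seed = seed))
}

# Random small multi-member network for enumeration property tests.
randomComplexNetwork <- function(seed, maxNodes = 4L, maxMembers = 4L) {
    set.seed(seed)
    k <- sample(2:maxNodes, 1L)
    nodes <- lapply(seq_len(k), function(i)
        sprintf("n%d_g%d", i, seq_len(sample.int(maxMembers, 1L))))
    names(nodes) <- sprintf("N%d", seq_len(k))
    edges <- lapply(seq_len(k - 1L),
        function(i) c(sprintf("N%d", i), sprintf("N%d", i + 1L)))
    PathwayNetwork(sprintf("rnd%d", seed), nodes = nodes, edges = edges)
}

# 5-node chain with three interior complex nodes (2 members each) gives
# 8 alternative models; decoy members are independent noise, so wrong
# substitutions break the covariance structure instead of producing an
# equivalent model. The true alternative is deliberately not the first in
# enumeration order.
selectionExperiment <- function(seed, n = 1000L,
                                coefs = c(0.7, 0.6, 0.5, 0.6),
                                caseShift = 0) {
    net <- PathwayNetwork("sel",
        nodes = list(A = "g1", B = c("d2", "g2"), C = c("d3", "g3"),
            D = c("g4", "d4"), E = "g5"),
        edges = list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E")))
    keys <- c("g1->g2", "g2->g3", "g3->g4", "g4->g5")
    coCtl <- setNames(coefs, keys)
    coCase <- coCtl
    coCase[1L] <- coCase[1L] + caseShift
    truth <- enumerateAlternatives(net)[[7L]]  # B->g2, C->g3, D->g4
    stopifnot(identical(unname(truth@assignment),
        c("g1", "g2", "g3", "g4", "g5")))
    cfg <- simulationConfig(truth,
        coefficients = list(SCZ = coCase, CTL = coCtl),
        nPerGroup = c(SCZ = n, CTL = n), seed = seed,
        background = list(nGenes = 3L, fractionInflated = 0,
            inflationFactor = 1, targetGroup = "SCZ"))
    sim <- simulatePathwayExpression(cfg)
    bg <- simulateBackgroundGenes(cfg)
    rownames(bg) <- c("d2", "d3", "d4")
    mat <- rbind(SummarizedExperiment::assay(sim$data),
        SummarizedExperiment::assay(bg))
    data <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = mat),
        colData = SummarizedExperiment::colData(sim$data))
    list(network = net, data = data, truthIndex = 7L, truth = sim$truth)
}

# Trapezoidal ROC-curve integration, an oracle for the rank-based C-index.
rocAreaTrapezoid <- function(scores, labels) {
    labels <- as.logical(labels)
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1L))
    fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1L))
    tpr <- c(0, tpr, 1)
    fpr <- c(0, fpr, 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

assayOf <- function(x) SummarizedExperiment::assay(x)
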