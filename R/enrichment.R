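#' EASE-penalized over-representation p-value
#'
#' One-tailed Fisher exact (hypergeometric upper-tail) p-value computed
#' after removing one hit from the overlap cell (floored at 0), the
#' conservative EASE variant of gene-set over-representation.
#'
#' @param hitsInSet number of flagged genes in the set.
#' @param setSize number of genes in the set.
#' @param hitsUniverse number of flagged genes in the universe.
#' @param universeSize number of genes in the universe.
#' @return p-value in (0, 1].
#' @export
easeOra <- function(hitsInSet, setSize, hitsUniverse, universeSize) {
    if (hitsInSet > setSize || setSize > universeSize ||
        hitsUniverse > universeSize || hitsInSet > hitsUniverse)
        stop("inconsistent contingency counts")
    a <- max(hitsInSet - 1L, 0L)
    # P(X >= a) for X ~ Hypergeom(universe, hitsUniverse, setSize)
    phyper(a - 1L, hitsUniverse, universeSize - hitsUniverse, setSize,
        lower.tail = FALSE)
}

#' Node-based over-representation analysis with a permutation null
#'
#' The enrichment score of a pathway network is the number of nodes
#' containing at least one gene flagged (e.g., increased variance in the
#' case group). The null distribution is approximated by permuting the
#' flags across the gene universe without replacement; the p-value is the
#' add-one-smoothed proportion of trials with a score at least as large
#' as observed.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param indicator named logical vector over the gene universe (names =
#'   gene symbols); every network member gene must be present.
#' @param nTrials number of permutation trials (default 10^6).
#' @param seed RNG seed for the trials.
#' @return data.frame row: \code{pathway}, \code{method}, \code{score}
#'   (observed node score), \code{p}, \code{nTrials}, \code{seed}.
#' @export
nodeOra <- function(network, indicator, nTrials = 1e6L, seed = 1L) {
    stopifnot(is(network, "PathwayNetwork"), nTrials >= 1)
    if (is.null(names(indicator)))
        stop("'indicator' must be named by gene symbol")
    members <- network@members
    allMembers <- unique(unlist(members, use.names = FALSE))
    miss <- setdiff(allMembers, names(indicator))
    if (length(miss))
        stop("member gene(s) missing from the universe: ",
            paste(miss, collapse = ", "))
    flags <- as.logical(indicator)
    obs <- sum(vapply(members,
        function(m) any(indicator[m]), logical(1L)))
    memberIdx <- lapply(members, function(m) match(m, allMembers))
    set.seed(seed)
    extreme <- .nodeOraTrials(
        memberIndex = as.integer(unlist(memberIdx)),
        nodeSizes = vapply(memberIdx, length, integer(1L)),
        nMembers = length(allMembers),
        nGenes = length(flags),
        nFlagged = sum(flags),
        observedScore = as.integer(obs),
        nTrials = as.integer(nTrials))
    data.frame(pathway = network@name, method = "node-ORA",
        score = obs, p = (1 + extreme) / (1 + nTrials),
        nTrials = as.integer(nTrials), seed = seed)
}

#' Preranked gene-set enrichment statistic
#'
#' Classic weighted Kolmogorov-Smirnov-style enrichment score (weight
#' exponent 1) over a ranked gene list, with a gene-label permutation
#' null. The p-value is one-sided on the side of the observed score's
#' sign, computed among the same-signed permutation scores with add-one
#' smoothing.
#'
#' @param rankedGenes named numeric vector of ranking scores, ordered from
#'   most to least interesting (the order of the vector is the ranking).
#' @param geneSet character vector of gene symbols.
#' @param nPermutations number of gene-label permutations (default 1000).
#' @param seed RNG seed.
#' @return list with \code{ES}, \code{p}, \code{nPermutations},
#'   \code{testable}; an empty intersection gives
#'   \code{testable = FALSE} with NA statistics.
#' @export
gseaPreranked <- function(rankedGenes, geneSet, nPermutations = 1000L,
                          seed = 1L) {
    stopifnot(all(is.finite(rankedGenes)))
    genes <- names(rankedGenes)
    inSet <- genes %in% geneSet
    if (!any(inSet))
        return(list(ES = NA_real_, p = NA_real_,
            nPermutations = as.integer(nPermutations), testable = FALSE))
    esStat <- function(hits) {
        w <- abs(rankedGenes)
        nr <- sum(w[hits])
        N <- length(hits)
        nh <- sum(hits)
        if (nr == 0) {
            # all-zero weights degenerate to the unweighted statistic
            inc <- ifelse(hits, 1 / nh, -1 / (N - nh))
        } else {
            inc <- ifelse(hits, w / nr, -1 / (N - nh))
        }
        run <- cumsum(inc)
        run[which.max(abs(run))]
    }
    es <- esStat(inSet)
    set.seed(seed)
    nh <- sum(inSet)
    perm <- vapply(seq_len(nPermutations), function(i) {
        h <- logical(length(inSet))
        h[sample.int(length(inSet), nh)] <- TRUE
        esStat(h)
    }, numeric(1L))
    if (es >= 0) {
        p <- (1 + sum(perm >= es)) / (1 + sum(perm >= 0))
    } else {
        p <- (1 + sum(perm <= es)) / (1 + sum(perm < 0))
    }
    list(ES = es, p = min(p, 1), nPermutations = as.integer(nPermutations),
        testable = TRUE)
}

.fisherCombine <- function(p) {
    p <- pmax(p, .Machine$double.xmin)
    stat <- -2 * sum(log(p))
    pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Node-based gene-set analysis by Fisher's method
#'
#' Two-stage aggregation of per-gene p-values (e.g., one-sided Levene
#' tests): member-gene p-values are combined within each node by Fisher's
#' statistic \eqn{-2\sum \ln p \sim \chi^2(2m)}, and the node-level
#' p-values are combined across the pathway by Fisher's method again.
#' Zero p-values are clamped to the smallest positive double with a
#' warning.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param genePvalues named numeric vector of per-gene p-values; every
#'   member gene must be present.
#' @param twoStage if \code{FALSE}, combine all member-gene p-values in a
#'   single Fisher stage (pooled-genes alternative).
#' @return pathway-level p-value in (0, 1].
#' @export
nodeGsaFisher <- function(network, genePvalues, twoStage = TRUE) {
    stopifnot(is(network, "PathwayNetwork"))
    members <- network@members
    allMembers <- unique(unlist(members, use.names = FALSE))
    miss <- setdiff(allMembers, names(genePvalues))
    if (length(miss))
        stop("member gene(s) without a p-value: ",
            paste(miss, collapse = ", "))
    if (any(genePvalues[allMembers] == 0))
        warning("zero p-value(s) clamped to the smallest positive double")
    if (!twoStage)
        return(.fisherCombine(genePvalues[allMembers]))
    nodeP <- vapply(members, function(m) .fisherCombine(genePvalues[m]),
        numeric(1L))
    .fisherCombine(nodeP)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, mapped back
#' to the input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bhFdr <- function(pvalues) {
    stopifnot(all(pvalues > 0 & pvalues <= 1))
    stats::p.adjust(pvalues, method = "BH")
}

#' Run all four enrichment procedures over a set of pathways
#'
#' For each pathway network: EASE over-representation and node-based
#' permutation ORA on the increased-variance indicator, and preranked GSEA
#' plus node-based Fisher gene-set analysis on the per-gene Levene
#' p-values (genes ranked by ascending p). FDR adjustment is applied per
#' method across pathways.
#'
#' @param networks named list of \linkS4class{PathwayNetwork}s.
#' @param indicator named logical increased-variance flags over the
#'   analysis universe.
#' @param genePvalues named numeric per-gene Levene p-values over the same
#'   universe.
#' @param nTrials permutation trials for the node-based ORA.
#' @param nPermutations permutations for preranked GSEA.
#' @param seed RNG seed.
#' @return data.frame with one row per (pathway, method): \code{pathway},
#'   \code{method}, \code{score}, \code{p}, \code{fdr}, \code{n} (trials
#'   or permutations where applicable), \code{seed}.
#' @export
enrichmentAnalysis <- function(networks, indicator, genePvalues,
                               nTrials = 1e5L, nPermutations = 1000L,
                               seed = 1L) {
    stopifnot(length(networks) >= 1L)
    universe <- names(indicator)
    hitsUniverse <- sum(indicator)
    ranked <- sort(genePvalues)
    # rank by ascending p; use -log10 p as the weighting score
    rankScores <- -log10(pmax(ranked, .Machine$double.xmin))
    rows <- list()
    for (i in seq_along(networks)) {
        net <- networks[[i]]
        memb <- intersect(uniqueGenes(net), universe)
        if (length(memb) < length(uniqueGenes(net)))
            stop("pathway '", net@name,
                "' has member genes outside the universe")
        ease <- easeOra(sum(indicator[memb]), length(memb), hitsUniverse,
            length(universe))
        rows[[length(rows) + 1L]] <- data.frame(pathway = net@name,
            method = "EASE-ORA", score = sum(indicator[memb]), p = ease,
            n = NA_integer_, seed = seed)
        no <- nodeOra(net, indicator, nTrials = nTrials,
            seed = seed + i)
        rows[[length(rows) + 1L]] <- data.frame(pathway = net@name,
            method = "node-ORA", score = no$score, p = no$p,
            n = as.integer(nTrials), seed = seed + i)
        gs <- gseaPreranked(rankScores, memb,
            nPermutations = nPermutations, seed = seed + i)
        rows[[length(rows) + 1L]] <- data.frame(pathway = net@name,
            method = "GSEA", score = gs$ES, p = gs$p,
            n = as.integer(nPermutations), seed = seed + i)
        fp <- nodeGsaFisher(net, genePvalues)
        rows[[length(rows) + 1L]] <- data.frame(pathway = net@name,
            method = "node-GSA-Fisher", score = NA_real_, p = fp,
            n = NA_integer_, seed = seed)
    }
    out <- do.call(rbind, rows)
    out$fdr <- NA_real_
    for (m in unique(out$method)) {
        ix <- out$method == m & !is.na(out$p)
        out$fdr[ix] <- bhFdr(out$p[ix])
    }
    rownames(out) <- NULL
    out
}
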