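#' Configuration for the truth-known two-group generator
#'
#' Describes a linear structural system over a resolved pathway network
#' with group-specific path coefficients, shared covariate effects and
#' Gaussian structural/measurement errors, plus a genome-wide background
#' of independent genes in which a configurable fraction has inflated
#' variance in one group.
#'
#' @slot network a \linkS4class{ResolvedNetwork} (one gene per node).
#' @slot coefficients named list, group -> named numeric of edge
#'   coefficients keyed \code{"SRC->DST"} over resolved variable names
#'   (gene symbols; latent nodes use the node id, and the loading onto
#'   their indicator gene is the edge \code{"nodeId->gene"}).
#' @slot errorVariances named positive numeric over model variables;
#'   latent variables are always generated with structural error variance 1
#'   (reference scaling, mean 0).
#' @slot covariateEffects variables-by-covariate numeric matrix of shared
#'   (group-equal) covariate effects, columns among \code{age, sex, PC1,
#'   PC2, batch2, batch3}; or a 0-column matrix for none.
#' @slot nPerGroup named integer vector of per-group sample sizes (>= 3).
#' @slot background list with \code{nGenes}, \code{fractionInflated},
#'   \code{inflationFactor} (>= 1) and \code{targetGroup}.
#' @slot seed master seed; stage-specific child seeds are derived from it
#'   deterministically.
#' @aliases SimulationConfig
#' @export
setClass("SimulationConfig",
    representation(
        network = "ResolvedNetwork", coefficients = "list",
        errorVariances = "numeric", covariateEffects = "matrix",
        nPerGroup = "numeric", background = "list", seed = "numeric"
    )
)

.simVariables <- function(resolved) {
    lat <- names(resolved@assignment)[resolved@latent]
    varOf <- ifelse(names(resolved@assignment) %in% lat,
        names(resolved@assignment), resolved@assignment)
    names(varOf) <- names(resolved@assignment)
    e <- resolved@edges
    edges <- if (nrow(e)) cbind(varOf[e[, 1L]], varOf[e[, 2L]]) else
        matrix(character(), ncol = 2L)
    if (length(lat))
        edges <- rbind(edges, cbind(lat, unname(resolved@assignment[lat])))
    observed <- unname(c(resolved@assignment[!resolved@latent],
        resolved@assignment[resolved@latent]))
    vars <- unique(c(unname(varOf), observed))
    list(vars = vars, observed = observed, latent = lat,
        edges = edges, edgeKeys = if (nrow(edges))
            paste0(edges[, 1L], "->", edges[, 2L]) else character())
}

setValidity("SimulationConfig", function(object) {
    msg <- character()
    sv <- .simVariables(object@network)
    if (length(object@coefficients) < 2L)
        msg <- c(msg, "at least two groups of coefficients are required")
    if (is.null(names(object@coefficients)))
        msg <- c(msg, "coefficients must be named by group")
    for (g in names(object@coefficients)) {
        bad <- setdiff(names(object@coefficients[[g]]), sv$edgeKeys)
        if (length(bad))
            msg <- c(msg, sprintf("group '%s' has coefficient(s) for edges not in the network: %s",
                g, paste(bad, collapse = ", ")))
    }
    ev <- object@errorVariances
    if (any(ev <= 0))
        msg <- c(msg, "error variances must be positive")
    if (!setequal(names(object@coefficients), names(object@nPerGroup)))
        msg <- c(msg, "nPerGroup groups must match coefficient groups")
    if (any(object@nPerGroup < 3))
        msg <- c(msg, "each group needs n >= 3")
    bg <- object@background
    need <- c("nGenes", "fractionInflated", "inflationFactor", "targetGroup")
    if (!all(need %in% names(bg))) {
        msg <- c(msg, "background must have fields nGenes, fractionInflated, inflationFactor, targetGroup")
    } else {
        if (bg$inflationFactor < 1)
            msg <- c(msg, "background inflationFactor must be >= 1")
        if (bg$fractionInflated < 0 || bg$fractionInflated > 1)
            msg <- c(msg, "background fractionInflated must be in [0, 1]")
        if (bg$nGenes > 0 &&
            !bg$targetGroup %in% names(object@coefficients))
            msg <- c(msg, "background targetGroup must be one of the groups")
    }
    if (ncol(object@covariateEffects) > 0) {
        okCols <- c("age", "sex", "PC1", "PC2", "batch2", "batch3")
        bad <- setdiff(colnames(object@covariateEffects), okCols)
        if (length(bad))
            msg <- c(msg, paste("unknown covariate column(s):",
                paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param network a \linkS4class{ResolvedNetwork}, or a
#'   \linkS4class{PathwayNetwork} whose nodes are all single-member (it is
#'   then resolved trivially).
#' @param coefficients named list, group -> named numeric of edge
#'   coefficients (\code{"SRC->DST"}). Edges omitted in a group default
#'   to 0.
#' @param errorVariances named positive numeric; variables omitted default
#'   to 1.
#' @param covariateEffects optional variables-by-covariate matrix of
#'   shared covariate effects (see \linkS4class{SimulationConfig}).
#' @param nPerGroup named integer vector of per-group sample sizes.
#' @param background list(nGenes, fractionInflated, inflationFactor,
#'   targetGroup); defaults to no background genes.
#' @param seed master seed.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(network, coefficients, errorVariances = numeric(),
                             covariateEffects = NULL, nPerGroup,
                             background = NULL, seed = 1L) {
    if (is(network, "PathwayNetwork")) {
        if (countAlternatives(network) != 1L)
            stop("pass a ResolvedNetwork for networks with complex nodes")
        network <- enumerateAlternatives(network)[[1L]]
    }
    sv <- .simVariables(network)
    ev <- setNames(rep(1, length(sv$vars)), sv$vars)
    ev[names(errorVariances)] <- errorVariances
    ev[sv$latent] <- 1
    if (is.null(covariateEffects))
        covariateEffects <- matrix(numeric(), nrow = length(sv$vars),
            ncol = 0, dimnames = list(sv$vars, NULL))
    if (is.null(background))
        background <- list(nGenes = 0L, fractionInflated = 0,
            inflationFactor = 1, targetGroup = names(coefficients)[1L])
    new("SimulationConfig", network = network, coefficients = coefficients,
        errorVariances = ev, covariateEffects = covariateEffects,
        nPerGroup = setNames(as.numeric(nPerGroup), names(nPerGroup)),
        background = background, seed = as.numeric(seed))
}

.childSeeds <- function(seed, n = 2L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
}

.drawCovariates <- function(n) {
    age <- sample(18:65, n, replace = TRUE)
    sex <- rbinom(n, 1L, 0.5)
    batch <- sample(1:3, n, replace = TRUE)
    data.frame(age = age, sex = sex, batch = factor(batch, levels = 1:3),
        PC1 = rnorm(n), PC2 = rnorm(n))
}

.covariateColumns <- function(cov) {
    cbind(age = cov$age, sex = cov$sex, PC1 = cov$PC1, PC2 = cov$PC2,
        batch2 = as.numeric(cov$batch == 2), batch3 = as.numeric(cov$batch == 3))
}

#' Simulate two-group pathway expression from the structural model
#'
#' For each group, samples are draws from the linear structural system
#' solved for the observed variables: errors and latent residuals are
#' Gaussian with the configured variances, covariate effects are shared
#' across groups, and per-group path coefficients define the reduced form
#' \eqn{u = (I-A_g)^{-1}(C c + \zeta)}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{data} (a \code{SummarizedExperiment}, genes x
#'   samples, \code{colData} columns \code{group, age, sex, batch, PC1,
#'   PC2}) and \code{truth} (per-group implied covariance of the observed
#'   genes conditional on covariates, the edges whose coefficients differ
#'   between groups, and the exact generating parameters).
#' @export
simulatePathwayExpression <- function(config) {
    validObject(config)
    sv <- .simVariables(config@network)
    V <- sv$vars
    nV <- length(V)
    groups <- names(config@coefficients)
    seeds <- .childSeeds(config@seed, 2L)
    set.seed(seeds[1L])

    Ceff <- matrix(0, nV, 6, dimnames = list(V,
        c("age", "sex", "PC1", "PC2", "batch2", "batch3")))
    if (ncol(config@covariateEffects) > 0)
        Ceff[rownames(config@covariateEffects),
            colnames(config@covariateEffects)] <- config@covariateEffects

    psi <- config@errorVariances[V]
    impliedByGroup <- list()
    exprList <- list()
    covList <- list()
    for (g in groups) {
        n <- config@nPerGroup[[g]]
        A <- matrix(0, nV, nV, dimnames = list(V, V))
        co <- config@coefficients[[g]]
        if (length(co)) {
            ek <- match(names(co), sv$edgeKeys)
            for (j in seq_along(co))
                A[sv$edges[ek[j], 2L], sv$edges[ek[j], 1L]] <- co[j]
        }
        E <- tryCatch(solve(diag(nV) - A), error = function(e)
            stop("singular (I - B) for group '", g,
                "': the structural system has no reduced form"))
        Tfull <- E %*% diag(psi, nV) %*% t(E)
        impliedByGroup[[g]] <- Tfull[sv$observed, sv$observed]
        cov <- .drawCovariates(n)
        Cc <- .covariateColumns(cov)
        Zeta <- matrix(rnorm(n * nV), n, nV) %*% diag(sqrt(psi), nV)
        U <- (Zeta + Cc %*% t(Ceff)) %*% t(E)
        colnames(U) <- V
        exprList[[g]] <- t(U[, sv$observed, drop = FALSE])
        cov$group <- g
        covList[[g]] <- cov
    }
    mat <- do.call(cbind, exprList)
    cd <- do.call(rbind, covList)
    colnames(mat) <- sprintf("%s_%03d", cd$group, unlist(lapply(
        groups, function(g) seq_len(config@nPerGroup[[g]]))))
    rownames(cd) <- colnames(mat)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = mat),
        colData = S4Vectors::DataFrame(cd[, c("group", "age", "sex",
            "batch", "PC1", "PC2")]))
    allKeys <- sv$edgeKeys
    differing <- allKeys[vapply(allKeys, function(k) {
        vals <- vapply(groups, function(g) {
            co <- config@coefficients[[g]]
            if (k %in% names(co)) unname(co[[k]]) else 0
        }, numeric(1L))
        max(vals) - min(vals) > 0
    }, logical(1L))]
    truth <- list(impliedCovariance = impliedByGroup,
        differingEdges = differing, coefficients = config@coefficients,
        errorVariances = psi, covariateEffects = Ceff)
    list(data = se, truth = truth)
}

#' Simulate a genome-wide background of independent genes
#'
#' Independent Gaussian genes; a configured fraction has its variance
#' multiplied by \code{inflationFactor} in the target group. Mirrors the
#' genome-wide variance comparison that the variance statistics and
#' enrichment stages consume.
#'
#' @param config a \linkS4class{SimulationConfig} with
#'   \code{background$nGenes >= 1}.
#' @return a \code{SummarizedExperiment} with an \code{inflated} logical
#'   column in \code{rowData} (the truth indicator) and \code{group} in
#'   \code{colData}.
#' @export
simulateBackgroundGenes <- function(config) {
    validObject(config)
    bg <- config@background
    if (bg$nGenes < 1) stop("background nGenes must be >= 1")
    groups <- names(config@coefficients)
    seeds <- .childSeeds(config@seed, 2L)
    set.seed(seeds[2L])
    nG <- as.integer(bg$nGenes)
    nInfl <- round(bg$fractionInflated * nG)
    inflated <- rep(FALSE, nG)
    if (nInfl > 0) inflated[sample.int(nG, nInfl)] <- TRUE
    mats <- lapply(groups, function(g) {
        n <- config@nPerGroup[[g]]
        m <- matrix(rnorm(nG * n), nG, n)
        if (g == bg$targetGroup && any(inflated))
            m[inflated, ] <- m[inflated, , drop = FALSE] *
                sqrt(bg$inflationFactor)
        m
    })
    mat <- do.call(cbind, mats)
    rownames(mat) <- sprintf("BG%05d", seq_len(nG))
    grp <- rep(groups, config@nPerGroup[groups])
    colnames(mat) <- sprintf("%s_bg%03d", grp, unlist(lapply(groups,
        function(g) seq_len(config@nPerGroup[[g]]))))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = mat),
        rowData = S4Vectors::DataFrame(inflated = inflated),
        colData = S4Vectors::DataFrame(group = grp,
            row.names = colnames(mat)))
}

#' Wrap an expression matrix and sample annotations
#'
#' @param mat genes-by-samples numeric matrix with rownames.
#' @param group per-sample group labels.
#' @param covariates optional data.frame of per-sample covariates.
#' @return a \code{SummarizedExperiment}.
#' @export
expressionDataset <- function(mat, group, covariates = NULL) {
    stopifnot(ncol(mat) == length(group))
    cd <- data.frame(group = as.character(group))
    if (!is.null(covariates)) cd <- cbind(cd, covariates)
    rownames(cd) <- colnames(mat)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = as.matrix(mat)),
        colData = S4Vectors::DataFrame(cd))
}

#' Split a dataset into per-group SummarizedExperiments
#'
#' @param data a \code{SummarizedExperiment} with a \code{group} column in
#'   \code{colData}.
#' @return named list of per-group \code{SummarizedExperiment}s.
#' @export
splitByGroup <- function(data) {
    grp <- SummarizedExperiment::colData(data)$group
    if (is.null(grp)) stop("colData must contain a 'group' column")
    lapply(split(seq_along(grp), grp), function(ix) data[, ix])
}

#' Bundled two-pathway demonstration dataset
#'
#' A truth-known dataset emulating the study design this workflow targets:
#' 144 case and 111 control samples; the serine-biosynthesis pathway
#' genes follow the structural model with stronger path coefficients in
#' the case group (inflating downstream variance) and a sign-flipped
#' PSPH -> SHMT2 path; the neurotrophin-pathway genes are null background
#' (independent noise); plus an anonymous genome-wide background in which
#' 30 percent of genes have 2x variance in the case group.
#'
#' @param seed master seed (default 20).
#' @param nCase,nControl per-group sample sizes.
#' @param nBackground number of anonymous background genes (default 400).
#' @return list with \code{data} (a \code{SummarizedExperiment}),
#'   \code{networks} (serine + neurotrophin \linkS4class{PathwayNetwork}),
#'   and \code{truth} (generating parameters and inflation indicator).
#' @export
demoDataset <- function(seed = 20L, nCase = 144L, nControl = 111L,
                        nBackground = 400L) {
    serine <- bundledNetworks("serine_biosynthesis")
    neuro <- bundledNetworks("neurotrophin")
    ctl <- c("PHGDH->PSAT1" = 0.6, "PSAT1->PSPH" = 0.6,
        "PSPH->SHMT1" = 0.5, "PSPH->SHMT2" = 0.5)
    scz <- c("PHGDH->PSAT1" = 1.1, "PSAT1->PSPH" = 1.0,
        "PSPH->SHMT1" = 1.0, "PSPH->SHMT2" = -0.6)
    cfg <- simulationConfig(serine,
        coefficients = list(SCZ = scz, CTL = ctl),
        covariateEffects = matrix(0.3,
            nrow = length(uniqueGenes(serine)), ncol = 2,
            dimnames = list(uniqueGenes(serine), c("PC1", "sex"))),
        nPerGroup = c(SCZ = nCase, CTL = nControl),
        background = list(nGenes = nBackground + 11L,
            fractionInflated = 0.3, inflationFactor = 2,
            targetGroup = "SCZ"),
        seed = seed)
    sim <- simulatePathwayExpression(cfg)
    bg <- simulateBackgroundGenes(cfg)
    # 11 non-inflated background genes stand in for the (null)
    # neurotrophin genes, so that pathway carries no variance signal
    nullIdx <- which(!SummarizedExperiment::rowData(bg)$inflated)[1:11]
    rownames(bg)[nullIdx] <- uniqueGenes(neuro)
    mat <- rbind(SummarizedExperiment::assay(sim$data),
        SummarizedExperiment::assay(bg))
    data <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = mat),
        colData = SummarizedExperiment::colData(sim$data))
    inflated <- SummarizedExperiment::rowData(bg)$inflated
    list(data = data,
        networks = list(serine = serine, neurotrophin = neuro),
        truth = list(pathway = sim$truth,
            backgroundInflated = setNames(inflated, rownames(bg))))
}
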