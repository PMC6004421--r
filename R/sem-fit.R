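#' Single-group SEM fit result
#'
#' @slot model the fitted \linkS4class{SemModel}.
#' @slot estimates named parameter estimates (free parameters).
#' @slot se named standard errors (NA when not identifiable).
#' @slot vcov parameter covariance matrix (inverse observed information).
#' @slot S sample covariance (unbiased, n-1 denominator).
#' @slot Sigma implied covariance at the optimum.
#' @slot Fml maximum-likelihood discrepancy at the optimum.
#' @slot logLik Gaussian log-likelihood at the optimum.
#' @slot n,p sample size and number of observed variables.
#' @slot converged,identifiable logical flags.
#' @slot diagnostics character vector naming any identifiability failures.
#' @slot gradNorm gradient norm at the reported optimum.
#' @aliases FitResult
#' @export
setClass("FitResult",
    representation(
        model = "SemModel", estimates = "numeric", se = "numeric",
        vcov = "matrix", S = "matrix", Sigma = "matrix", Fml = "numeric",
        logLik = "numeric", n = "numeric", p = "numeric",
        converged = "logical", identifiable = "logical",
        diagnostics = "character", gradNorm = "numeric"
    )
)

setMethod("show", "FitResult", function(object) {
    cat(sprintf(
        "FitResult: n=%d, p=%d, F_ML=%.6g, converged=%s, identifiable=%s\n",
        object@n, object@p, object@Fml, object@converged,
        object@identifiable))
    if (length(object@diagnostics))
        cat("  diagnostics:", paste(object@diagnostics, collapse = "; "),
            "\n")
})

#' Multigroup SEM fit
#'
#' @slot fits named list of per-group \linkS4class{FitResult}.
#' @slot model the common \linkS4class{SemModel}.
#' @slot groups group labels.
#' @slot constraints \code{"none"} (all structural parameters
#'   group-specific) or \code{"all"} (every structural parameter equal
#'   across groups).
#' @slot chisq,df joint chi-square \eqn{\sum_g (n_g-1) F_g} and its degrees
#'   of freedom.
#' @slot baselineChisq,baselineDf independence-baseline statistics.
#' @slot wald per-path between-group Wald table.
#' @slot sharedSlopes matrix of covariate-equation slopes (shared across
#'   groups), or a 0-column matrix when no covariates were used.
#' @slot kPerGroup per-group parameter counts used for AIC/BIC (free
#'   structural parameters plus an equal share of shared covariate slopes).
#' @slot aic,bic,logLikPerGroup named per-group information criteria.
#' @aliases MultigroupFit
#' @export
setClass("MultigroupFit",
    representation(
        fits = "list", model = "SemModel", groups = "character",
        constraints = "character", chisq = "numeric", df = "numeric",
        baselineChisq = "numeric", baselineDf = "numeric",
        wald = "data.frame", sharedSlopes = "matrix",
        kPerGroup = "numeric", aic = "numeric", bic = "numeric",
        logLikPerGroup = "numeric"
    )
)

setMethod("show", "MultigroupFit", function(object) {
    idx <- fitIndices(object)
    cat(sprintf(
        "MultigroupFit over groups %s: chisq=%.4g (df=%d), RMSEA=%.4g, CFI=%.4g\n",
        paste(object@groups, collapse = "/"), object@chisq, object@df,
        idx$rmsea, idx$cfi))
    cat(sprintf("  identifiable: %s\n",
        paste(vapply(object@fits, slot, logical(1L), "identifiable"),
            collapse = "/")))
})

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' \eqn{F_{ML} = \ln|\Sigma| + tr(S\Sigma^{-1}) - \ln|S| - p}, the
#' Kullback-Leibler-type divergence minimized by covariance-structure ML.
#'
#' @param S sample covariance matrix (positive definite).
#' @param Sigma model-implied covariance matrix (positive definite, same
#'   dimension).
#' @return nonnegative scalar; 0 iff \code{Sigma == S}.
#' @export
mlDiscrepancy <- function(S, Sigma) {
    p <- nrow(S)
    stopifnot(nrow(Sigma) == p, ncol(S) == p, ncol(Sigma) == p)
    chS <- tryCatch(chol(S), error = function(e)
        stop("S is not positive definite (condition estimate: ",
            format(kappa(S)), ")"))
    chSig <- tryCatch(chol(Sigma), error = function(e)
        stop("Sigma is not positive definite (condition estimate: ",
            format(kappa(Sigma)), ")"))
    SigInv <- chol2inv(chSig)
    val <- 2 * sum(log(diag(chSig))) + sum(SigInv * S) -
        2 * sum(log(diag(chS))) - p
    max(val, 0)
}

# ---- internal: compiled model structure for fast evaluation --------------

.compileModel <- function(model) {
    pt <- model@partable
    V <- model@variables
    nV <- length(V)
    p <- length(model@observed)
    stopifnot(identical(V[seq_len(p)], model@observed))
    idx <- function(v) match(v, V)
    pos <- integer(nrow(pt))
    isA <- pt$op %in% c("~", "=~")
    for (i in seq_len(nrow(pt))) {
        pos[i] <- switch(pt$op[i],
            "~" = (idx(pt$rhs[i]) - 1L) * nV + idx(pt$lhs[i]),
            "=~" = (idx(pt$lhs[i]) - 1L) * nV + idx(pt$rhs[i]),
            "~~" = (idx(pt$lhs[i]) - 1L) * nV + idx(pt$lhs[i]))
    }
    freeRows <- which(pt$free)
    list(
        nV = nV, p = p, pt = pt, pos = pos, isA = isA,
        baseVal = ifelse(pt$free, 0, pt$value),
        freeRows = freeRows,
        freeIsVar = pt$op[freeRows] == "~~",
        freeIsA = isA[freeRows],
        labels = pt$label[freeRows],
        dupA = anyDuplicated(pos[isA]) > 0L,
        dupP = anyDuplicated(pos[!isA]) > 0L
    )
}

.ramMatrices <- function(cm, thetaRaw) {
    v <- cm$baseVal
    v[cm$freeRows] <- thetaRaw
    Af <- numeric(cm$nV * cm$nV)
    Pf <- numeric(cm$nV * cm$nV)
    if (cm$dupA) {
        s <- rowsum(v[cm$isA], cm$pos[cm$isA])
        Af[as.integer(rownames(s))] <- s
    } else Af[cm$pos[cm$isA]] <- v[cm$isA]
    if (cm$dupP) {
        s <- rowsum(v[!cm$isA], cm$pos[!cm$isA])
        Pf[as.integer(rownames(s))] <- s
    } else Pf[cm$pos[!cm$isA]] <- v[!cm$isA]
    list(A = matrix(Af, cm$nV), Psi = matrix(Pf, cm$nV))
}

# F_ML and its gradient w.r.t. the raw free parameters.
.evalModel <- function(cm, thetaRaw, S, ldS, wantGrad = TRUE) {
    ram <- .ramMatrices(cm, thetaRaw)
    ImA <- diag(cm$nV) - ram$A
    E <- tryCatch(solve(ImA), error = function(e) NULL)
    if (is.null(E)) return(NULL)
    Tfull <- E %*% ram$Psi %*% t(E)
    obs <- seq_len(cm$p)
    Sigma <- (Tfull[obs, obs, drop = FALSE] +
        t(Tfull[obs, obs, drop = FALSE])) / 2
    chSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(chSig)) return(NULL)
    SigInv <- chol2inv(chSig)
    Fval <- 2 * sum(log(diag(chSig))) + sum(SigInv * S) - ldS - cm$p
    out <- list(F = Fval, Sigma = Sigma, SigInv = SigInv)
    if (wantGrad) {
        W <- SigInv - SigInv %*% S %*% SigInv
        Wfull <- matrix(0, cm$nV, cm$nV)
        Wfull[obs, obs] <- W
        EtW <- crossprod(E, Wfull)
        gA <- 2 * (EtW %*% Tfull)
        gP <- EtW %*% E
        g <- numeric(length(cm$freeRows))
        fp <- cm$pos[cm$freeRows]
        g[cm$freeIsA] <- gA[fp[cm$freeIsA]]
        g[!cm$freeIsA] <- gP[fp[!cm$freeIsA]]
        out$grad <- g
    }
    out
}

.startValues <- function(cm, S) {
    pt <- cm$pt
    fr <- cm$freeRows
    th <- numeric(length(fr))
    dS <- diag(S)
    names(dS) <- colnames(S)
    for (j in seq_along(fr)) {
        i <- fr[j]
        th[j] <- switch(pt$op[i],
            "~" = 0.1,
            "=~" = 1.0,
            "~~" = {
                v <- dS[pt$lhs[i]]
                if (is.na(v)) 1.0 else max(0.5 * v, 1e-4)
            })
    }
    th
}

# Minimize F_ML over the free parameters (variances log-transformed).
.optimizeF <- function(cm, S, maxit = 500L, gradTol = 1e-6) {
    ldS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    toRaw <- function(x) { x[cm$freeIsVar] <- exp(x[cm$freeIsVar]); x }
    fn <- function(x) {
        r <- .evalModel(cm, toRaw(x), S, ldS, wantGrad = FALSE)
        if (is.null(r)) return(1e10 + sum(x^2))
        r$F
    }
    gr <- function(x) {
        raw <- toRaw(x)
        r <- .evalModel(cm, raw, S, ldS)
        if (is.null(r)) return(2 * x)
        g <- r$grad
        g[cm$freeIsVar] <- g[cm$freeIsVar] * raw[cm$freeIsVar]
        g
    }
    x0 <- .startValues(cm, S)
    x0[cm$freeIsVar] <- log(x0[cm$freeIsVar])
    opt <- optim(x0, fn, gr, method = "BFGS",
        control = list(maxit = maxit, reltol = 1e-12))
    g1 <- sqrt(sum(gr(opt$par)^2))
    if (g1 > gradTol) {
        opt2 <- optim(opt$par, fn, gr, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-14))
        if (opt2$value <= opt$value) opt <- opt2
    }
    raw <- toRaw(opt$par)
    gnorm <- sqrt(sum(.rawGrad(cm, raw, S, ldS)^2))
    list(thetaRaw = raw, F = opt$value, gradNorm = gnorm, ldS = ldS,
        converged = is.finite(opt$value) && opt$value < 1e9 &&
            gnorm < 1e-4)
}

.rawGrad <- function(cm, thetaRaw, S, ldS) {
    r <- .evalModel(cm, thetaRaw, S, ldS)
    if (is.null(r)) return(rep(NA_real_, length(thetaRaw)))
    r$grad
}

# Observed information of the (weight/2)-scaled objective by central
# differences of the analytic gradient (relative step 1e-5).
.observedInfo <- function(cm, thetaRaw, S, ldS, weight) {
    k <- length(thetaRaw)
    H <- matrix(NA_real_, k, k)
    for (j in seq_len(k)) {
        h <- 1e-5 * max(abs(thetaRaw[j]), 1)
        tp <- thetaRaw; tp[j] <- tp[j] + h
        tm <- thetaRaw; tm[j] <- tm[j] - h
        gp <- .rawGrad(cm, tp, S, ldS)
        gm <- .rawGrad(cm, tm, S, ldS)
        H[, j] <- (gp - gm) / (2 * h)
    }
    (weight / 2) * (H + t(H)) / 2
}

.identifiabilityVerdict <- function(converged, H, se, est, SigmaOk) {
    diag_ <- character()
    if (!converged) diag_ <- c(diag_, "optimizer did not converge")
    if (any(!is.finite(H))) {
        diag_ <- c(diag_, "information matrix could not be evaluated")
    } else {
        ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
        if (max(ev) <= 0 || min(ev) < 1e-8 * max(ev))
            diag_ <- c(diag_,
                "information matrix not positive definite")
    }
    if (any(!is.finite(se))) {
        diag_ <- c(diag_, "standard errors unavailable")
    } else if (any(se > 20 * abs(est) & se > 10)) {
        diag_ <- c(diag_, "exploding standard error(s)")
    }
    if (!SigmaOk)
        diag_ <- c(diag_, "implied covariance not positive definite")
    list(ok = length(diag_) == 0L, diagnostics = diag_)
}

.gaussianLogLik <- function(S, Sigma, n, p) {
    chSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(chSig)) return(NA_real_)
    SigInv <- chol2inv(chSig)
    Sml <- S * (n - 1) / n
    -(n / 2) * (p * log(2 * pi) + 2 * sum(log(diag(chSig))) +
        sum(SigInv * Sml))
}

.failedFit <- function(model, S, n, why) {
    k <- nFreeParams(model)
    lab <- paramLabels(model)
    new("FitResult", model = model,
        estimates = setNames(rep(NA_real_, k), lab),
        se = setNames(rep(NA_real_, k), lab),
        vcov = matrix(NA_real_, k, k), S = S,
        Sigma = matrix(NA_real_, nrow(S), ncol(S)), Fml = NA_real_,
        logLik = NA_real_, n = n, p = nrow(S), converged = FALSE,
        identifiable = FALSE, diagnostics = why, gradNorm = NA_real_)
}

# Core: fit the covariance structure to one covariance matrix.
.fitCovStructure <- function(model, S, n, weight = n - 1) {
    cm <- .compileModel(model)
    lab <- cm$labels
    chS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chS))
        return(.failedFit(model, S, n,
            "sample covariance not positive definite"))
    res <- .optimizeF(cm, S)
    H <- .observedInfo(cm, res$thetaRaw, S, res$ldS, weight)
    Vc <- tryCatch(solve(H), error = function(e)
        matrix(NA_real_, length(lab), length(lab)))
    se <- suppressWarnings(sqrt(diag(Vc)))
    ev <- .evalModel(cm, res$thetaRaw, S, res$ldS, wantGrad = FALSE)
    SigmaOk <- !is.null(ev)
    Sigma <- if (SigmaOk) ev$Sigma else matrix(NA_real_, nrow(S), ncol(S))
    verdict <- .identifiabilityVerdict(res$converged, H, se, res$thetaRaw,
        SigmaOk)
    if (!verdict$ok) se[] <- NA_real_
    new("FitResult", model = model,
        estimates = setNames(res$thetaRaw, lab),
        se = setNames(se, lab), vcov = Vc, S = S, Sigma = Sigma,
        Fml = res$F, logLik = .gaussianLogLik(S, Sigma, n, nrow(S)),
        n = n, p = nrow(S), converged = res$converged,
        identifiable = verdict$ok, diagnostics = verdict$diagnostics,
        gradNorm = res$gradNorm)
}

# Extract a variables x samples matrix for the model's observed variables.
.observedMatrix <- function(model, data) {
    if (is(data, "SummarizedExperiment"))
        data <- SummarizedExperiment::assay(data)
    if (is.data.frame(data)) data <- as.matrix(data)
    miss <- setdiff(model@observed, rownames(data))
    if (length(miss))
        stop("data is missing observed variable(s): ",
            paste(miss, collapse = ", "))
    m <- data[model@observed, , drop = FALSE]
    if (anyNA(m)) stop("missing values in data; complete data required")
    m
}

#' Fit a structural equation model to one group of samples
#'
#' Minimizes the maximum-likelihood discrepancy between the sample
#' covariance of the observed variables and the model-implied covariance.
#' Standard errors come from the inverse observed information of the
#' \eqn{(n-1)F_{ML}/2}-scaled objective (central-difference Hessian of the
#' analytic gradient).
#'
#' @param model a \linkS4class{SemModel}.
#' @param data a \code{SummarizedExperiment} or a numeric matrix with
#'   variables as rows (rownames) and samples as columns.
#' @return a \linkS4class{FitResult}. Non-convergence and empirical
#'   non-identifiability are flagged, not raised.
#' @export
fitSem <- function(model, data) {
    Y <- .observedMatrix(model, data)
    n <- ncol(Y)
    p <- nrow(Y)
    if (n <= p)
        stop(sprintf("n (%d) must exceed the number of observed variables (%d)",
            n, p))
    S <- cov(t(Y))
    .fitCovStructure(model, S, n)
}

# Shared-slope, group-intercept residualization for the covariate
# equations of a multigroup fit. Returns per-group residual matrices and
# the shared slope estimates.
.covariateResiduals <- function(Ys, covars) {
    groups <- names(Ys)
    ns <- vapply(Ys, ncol, integer(1L))
    Ypool <- do.call(cbind, Ys)
    glab <- factor(rep(groups, ns), levels = groups)
    if (is.null(covars)) {
        Xdf <- data.frame(.group = glab)
        form <- ~.group
    } else {
        Xdf <- do.call(rbind, lapply(covars, as.data.frame))
        Xdf$.group <- glab
        form <- ~.
    }
    X <- model.matrix(form, data = Xdf)
    if (qr(X)$rank < ncol(X))
        stop("covariate design is rank deficient; check columns: ",
            paste(colnames(X), collapse = ", "))
    qrX <- qr(X)
    resid <- t(qr.resid(qrX, t(Ypool)))
    beta <- t(qr.coef(qrX, t(Ypool)))
    slopeCols <- setdiff(colnames(X),
        c("(Intercept)", grep("^\\.group", colnames(X), value = TRUE)))
    slopes <- beta[, slopeCols, drop = FALSE]
    splitIdx <- split(seq_len(sum(ns)), glab)
    residByGroup <- lapply(splitIdx, function(ix) resid[, ix, drop = FALSE])
    list(resid = residByGroup, slopes = slopes, rankMean = ncol(X))
}

#' Fit a structural equation model to several groups simultaneously
#'
#' Covariate equations (one linear equation per observed variable with the
#' covariates as explanatory variables) are estimated with slopes
#' constrained equal across groups and group-specific intercepts; the
#' covariance structure is then fitted to the per-group residual
#' covariance matrices by minimizing \eqn{\sum_g (n_g - 1) F_g}. With
#' \code{constraints = "none"} every structural parameter is group-specific
#' and the joint optimum separates into per-group fits; with
#' \code{constraints = "all"} all structural parameters are equal across
#' groups, which is solved exactly as a single fit to the
#' \eqn{(n_g-1)}-weighted mean of the group covariance matrices.
#'
#' @param model a \linkS4class{SemModel}.
#' @param groups named list (>= 2) of \code{SummarizedExperiment}s or
#'   variables-by-samples matrices with identical variable sets.
#' @param covariates either \code{NULL}, a character vector of
#'   \code{colData} columns (when groups are SummarizedExperiments), or a
#'   named list of per-group data.frames of covariate values (rows =
#'   samples in column order).
#' @param constraints \code{"none"} (default) or \code{"all"}.
#' @return a \linkS4class{MultigroupFit}.
#' @export
fitMultigroup <- function(model, groups, covariates = NULL,
                          constraints = c("none", "all")) {
    constraints <- match.arg(constraints)
    if (length(groups) < 2L) stop("at least two groups are required")
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
        stop("'groups' must be a named list")
    Ys <- lapply(groups, function(g) .observedMatrix(model, g))
    p <- length(model@observed)
    ns <- vapply(Ys, ncol, numeric(1L))
    small <- ns <= p
    if (any(small))
        stop("group(s) with n <= p: ",
            paste(names(groups)[small], collapse = ", "))
    covdf <- NULL
    if (!is.null(covariates)) {
        if (is.character(covariates)) {
            covdf <- lapply(groups, function(g) {
                if (!is(g, "SummarizedExperiment"))
                    stop("character 'covariates' requires SummarizedExperiment groups")
                cd <- as.data.frame(SummarizedExperiment::colData(g))
                miss <- setdiff(covariates, colnames(cd))
                if (length(miss))
                    stop("missing covariate column(s): ",
                        paste(miss, collapse = ", "))
                cd[, covariates, drop = FALSE]
            })
        } else covdf <- covariates[names(groups)]
    }
    rr <- .covariateResiduals(Ys, covdf)
    Slist <- lapply(rr$resid, function(r) cov(t(r)))
    k <- nFreeParams(model)
    G <- length(groups)
    nShared <- if (is.null(covdf)) 0 else length(rr$slopes)

    if (constraints == "all") {
        w <- ns - 1
        Sbar <- Reduce(`+`, Map(`*`, Slist, w)) / sum(w)
        pooled <- .fitCovStructure(model, Sbar, sum(ns), weight = sum(w))
        fits <- lapply(names(groups), function(g) {
            f <- pooled
            f@S <- Slist[[g]]
            f@n <- ns[[g]]
            f@Fml <- if (f@converged)
                mlDiscrepancy(Slist[[g]], f@Sigma) else NA_real_
            f@logLik <- .gaussianLogLik(Slist[[g]], f@Sigma, ns[[g]], p)
            f
        })
        names(fits) <- names(groups)
        df <- G * p * (p + 1) / 2 - k
        kg <- setNames(rep((k + nShared) / G, G), names(groups))
    } else {
        fits <- Map(function(S, n) .fitCovStructure(model, S, n),
            Slist, ns)
        df <- G * p * (p + 1) / 2 - G * k
        kg <- setNames(rep(k + nShared / G, G), names(groups))
    }
    chisq <- sum(vapply(names(groups),
        function(g) (ns[[g]] - 1) * fits[[g]]@Fml, numeric(1L)))
    bchisq <- sum(vapply(names(groups), function(g) {
        S <- Slist[[g]]
        R <- stats::cov2cor(S)
        (ns[[g]] - 1) *
            (-as.numeric(determinant(R, logarithm = TRUE)$modulus))
    }, numeric(1L)))
    bdf <- G * p * (p + 1) / 2 - G * p
    ll <- vapply(fits, slot, numeric(1L), "logLik")
    aic <- -2 * ll + 2 * kg
    bic <- -2 * ll + kg * log(ns)
    slopes <- rr$slopes
    if (is.null(slopes)) slopes <- matrix(numeric(), nrow = p, ncol = 0)
    mg <- new("MultigroupFit", fits = fits, model = model,
        groups = names(groups), constraints = constraints,
        chisq = chisq, df = df, baselineChisq = bchisq, baselineDf = bdf,
        wald = data.frame(), sharedSlopes = slopes, kPerGroup = kg,
        aic = aic, bic = bic, logLikPerGroup = ll)
    mg@wald <- .waldTable(mg)
    mg
}

# Between-group Wald tests for all free structural paths (two-group case:
# first vs second group; more groups: all pairs against the first).
.waldTable <- function(fit) {
    if (fit@constraints == "all" || length(fit@groups) < 2L)
        return(data.frame())
    pt <- fit@model@partable
    pathLabs <- pt$label[pt$free & pt$op %in% c("~", "=~")]
    if (!length(pathLabs)) return(data.frame())
    g1 <- fit@groups[1L]
    g2 <- fit@groups[2L]
    f1 <- fit@fits[[g1]]
    f2 <- fit@fits[[g2]]
    e1 <- f1@estimates[pathLabs]; s1 <- f1@se[pathLabs]
    e2 <- f2@estimates[pathLabs]; s2 <- f2@se[pathLabs]
    z <- (e1 - e2) / sqrt(s1^2 + s2^2)
    pv <- 2 * pnorm(-abs(z))
    data.frame(path = pathLabs, est1 = unname(e1), se1 = unname(s1),
        est2 = unname(e2), se2 = unname(s2), z = unname(z), p = unname(pv),
        testable = is.finite(z), row.names = NULL)
}

#' Wald test of a path-coefficient difference between two groups
#'
#' \eqn{z = (\hat\theta_1 - \hat\theta_2) / \sqrt{SE_1^2 + SE_2^2}} with a
#' two-sided normal p-value.
#'
#' @param fit a \linkS4class{MultigroupFit} with \code{constraints="none"}.
#' @param edge either a parameter label (\code{"dst~src"}), an
#'   \code{"src->dst"} string, or a length-2 character vector
#'   \code{c(src, dst)}.
#' @return list with \code{z}, \code{p}, per-group \code{estimates} and
#'   \code{se}, and \code{testable}.
#' @export
waldDifferenceTest <- function(fit, edge) {
    stopifnot(is(fit, "MultigroupFit"))
    if (length(edge) == 2L) {
        lab <- paste0(edge[2L], "~", edge[1L])
    } else if (grepl("->", edge, fixed = TRUE)) {
        se <- strsplit(edge, "->", fixed = TRUE)[[1L]]
        lab <- paste0(se[2L], "~", se[1L])
    } else lab <- edge
    tab <- fit@wald
    row <- tab[tab$path == lab, , drop = FALSE]
    if (nrow(row) == 0L)
        stop("no free path '", lab, "' in the fitted model")
    if (!row$testable)
        return(list(z = NA_real_, p = NA_real_,
            estimates = c(row$est1, row$est2), se = c(row$se1, row$se2),
            testable = FALSE))
    list(z = row$z, p = row$p, estimates = c(row$est1, row$est2),
        se = c(row$se1, row$se2), testable = TRUE)
}

#' Fit indices for an SEM fit
#'
#' Chi-square \eqn{\sum_g (n_g-1)F_g}, RMSEA
#' \eqn{\sqrt{G}\sqrt{\max(\chi^2 - df, 0)/(df\,(N-G))}}, CFI against the
#' independence baseline (free variances only), and AIC/BIC.
#'
#' @param fit a \linkS4class{FitResult} or \linkS4class{MultigroupFit}.
#' @return list with \code{chisq}, \code{df}, \code{rmsea}, \code{cfi},
#'   \code{aic}, \code{bic}.
#' @export
setGeneric("fitIndices", function(fit) standardGeneric("fitIndices"))

.indicesFrom <- function(chisq, df, bchisq, bdf, N, G, aic, bic) {
    if (df <= 0) {
        warning("df = 0: RMSEA undefined, reported as 0")
        rmsea <- 0
    } else {
        rmsea <- sqrt(G) * sqrt(max(chisq - df, 0) / (df * (N - G)))
    }
    denom <- max(bchisq - bdf, chisq - df, 0)
    cfi <- if (denom == 0) 1 else 1 - max(chisq - df, 0) / denom
    cfi <- min(max(cfi, 0), 1)
    list(chisq = chisq, df = df, rmsea = rmsea, cfi = cfi, aic = aic,
        bic = bic)
}

#' @rdname fitIndices
setMethod("fitIndices", "FitResult", function(fit) {
    p <- fit@p
    k <- nFreeParams(fit@model)
    df <- p * (p + 1) / 2 - k
    chisq <- (fit@n - 1) * fit@Fml
    R <- stats::cov2cor(fit@S)
    bchisq <- (fit@n - 1) *
        (-as.numeric(determinant(R, logarithm = TRUE)$modulus))
    bdf <- p * (p + 1) / 2 - p
    .indicesFrom(chisq, df, bchisq, bdf, fit@n, 1L,
        aic = -2 * fit@logLik + 2 * k,
        bic = -2 * fit@logLik + k * log(fit@n))
})

#' @rdname fitIndices
setMethod("fitIndices", "MultigroupFit", function(fit) {
    N <- sum(vapply(fit@fits, slot, numeric(1L), "n"))
    .indicesFrom(fit@chisq, fit@df, fit@baselineChisq, fit@baselineDf,
        N, length(fit@groups), aic = fit@aic, bic = fit@bic)
})

#' Empirical identifiability verdict
#'
#' A fit is empirically identifiable when the optimizer converged, the
#' observed information matrix is positive definite (smallest eigenvalue
#' at least 1e-8 of the largest), no standard error explodes (> 20x the
#' estimate and > 10 in absolute value), and the implied covariance is
#' positive definite at the optimum.
#'
#' @param fit a \linkS4class{FitResult} or \linkS4class{MultigroupFit}.
#' @return logical; the \code{"diagnostics"} attribute names any
#'   triggering criteria (for a multigroup fit, per offending group).
#' @export
setGeneric("checkIdentifiability",
    function(fit) standardGeneric("checkIdentifiability"))

#' @rdname checkIdentifiability
setMethod("checkIdentifiability", "FitResult", function(fit) {
    structure(fit@identifiable, diagnostics = fit@diagnostics)
})

#' @rdname checkIdentifiability
setMethod("checkIdentifiability", "MultigroupFit", function(fit) {
    ok <- vapply(fit@fits, slot, logical(1L), "identifiable")
    dg <- unlist(Map(function(g, f) {
        if (length(f@diagnostics))
            paste0(g, ": ", f@diagnostics) else character()
    }, names(fit@fits), fit@fits), use.names = FALSE)
    structure(all(ok), diagnostics = dg)
})

#' Saturated model over a set of observed variables
#'
#' A just-identified recursive model (full lower-triangular DAG with free
#' variances) that can reproduce any positive-definite covariance; its
#' optimum has \eqn{F_{ML} = 0}. Mainly useful for testing and as a
#' reference.
#'
#' @param variables character vector of observed variable names.
#' @return a \linkS4class{SemModel}.
#' @export
saturatedModel <- function(variables) {
    stopifnot(length(variables) >= 1L)
    paths <- NULL
    if (length(variables) >= 2L) {
        idx <- which(lower.tri(diag(length(variables))), arr.ind = TRUE)
        paths <- cbind(variables[idx[, "col"]], variables[idx[, "row"]])
    }
    semModel(paths = paths)
}
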