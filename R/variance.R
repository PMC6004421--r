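.groupMatrices <- function(data, group = NULL) {
    if (is(data, "SummarizedExperiment")) {
        grp <- SummarizedExperiment::colData(data)$group
        mat <- SummarizedExperiment::assay(data)
    } else {
        mat <- as.matrix(data)
        grp <- group
    }
    if (is.null(grp)) stop("group labels are required")
    grp <- as.character(grp)
    ug <- unique(grp)
    if (length(ug) < 2L)
        stop("two sample groups are required; found: ",
            paste(ug, collapse = ", "))
    list(mat = mat, group = grp, levels = ug)
}

.rowVarsBy <- function(mat, idx) {
    n <- length(idx)
    m <- rowMeans(mat[, idx, drop = FALSE])
    rowSums((mat[, idx, drop = FALSE] - m)^2) / (n - 1)
}

#' Per-gene, per-group expression variances
#'
#' Unbiased (n-1 denominator) variances computed separately within each
#' group, plus the indicator of which genes have larger variance in the
#' case group. Ties (exactly equal variances) get an \code{NA} indicator
#' and are excluded from sign-test counts.
#'
#' @param data a \code{SummarizedExperiment} with a \code{group} colData
#'   column, or a genes-by-samples matrix.
#' @param group group labels (when \code{data} is a matrix).
#' @param case label of the case group (default: first level not equal to
#'   \code{control}, or the first group).
#' @param control label of the control group (default: second group).
#' @return data.frame with columns \code{gene}, \code{varCase},
#'   \code{varControl}, \code{caseGreater} (logical, NA on ties).
#' @export
groupVariances <- function(data, group = NULL, case = NULL, control = NULL) {
    gm <- .groupMatrices(data, group)
    if (is.null(case)) case <- gm$levels[1L]
    if (is.null(control)) control <- setdiff(gm$levels, case)[1L]
    ic <- which(gm$group == case)
    ik <- which(gm$group == control)
    if (length(ic) < 2L || length(ik) < 2L)
        stop("each group needs n >= 2 to estimate a variance")
    v1 <- .rowVarsBy(gm$mat, ic)
    v0 <- .rowVarsBy(gm$mat, ik)
    ind <- ifelse(v1 == v0, NA, v1 > v0)
    data.frame(gene = rownames(gm$mat), varCase = unname(v1),
        varControl = unname(v0), caseGreater = unname(ind),
        row.names = NULL)
}

#' One-sided exact sign test
#'
#' Exact binomial tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim Bin(n, 1/2)}: the p-value for observing at least \code{k}
#' genes with larger case-group variance among \code{n} informative
#' (untied) genes under the null that either group is equally likely to
#' have the larger variance.
#'
#' @param k number of genes with larger case-group variance.
#' @param n number of informative genes (ties excluded upstream).
#' @return one-sided p-value.
#' @export
signTest <- function(k, n) {
    stopifnot(n >= 1, k >= 0, k <= n)
    pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Residualize expression on covariates
#'
#' Per-gene least-squares residuals from regressing expression on the
#' supplied covariates over the pooled samples (an intercept is always
#' included). Stands in for normalization-model residuals when the input
#' matrix is already normalized.
#'
#' @param data a \code{SummarizedExperiment} or genes-by-samples matrix.
#' @param covariates data.frame of per-sample covariates, or (for a
#'   SummarizedExperiment) a character vector of colData columns.
#' @return genes-by-samples matrix of residuals (mean 0 per gene).
#' @export
residualize <- function(data, covariates) {
    if (is(data, "SummarizedExperiment")) {
        mat <- SummarizedExperiment::assay(data)
        if (is.character(covariates)) {
            cd <- as.data.frame(SummarizedExperiment::colData(data))
            miss <- setdiff(covariates, colnames(cd))
            if (length(miss))
                stop("missing covariate column(s): ",
                    paste(miss, collapse = ", "))
            covariates <- cd[, covariates, drop = FALSE]
        }
    } else mat <- as.matrix(data)
    stopifnot(nrow(covariates) == ncol(mat))
    X <- model.matrix(~., data = as.data.frame(covariates))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("covariate design is rank deficient; collinear column(s): ",
            paste(drop, collapse = ", "))
    }
    res <- t(qr.resid(qrX, t(mat)))
    dimnames(res) <- dimnames(mat)
    res
}

#' One-sided Levene test of variance inflation
#'
#' Classic Levene statistic specialized to two groups in its t form:
#' absolute deviations from the group centers are compared by a pooled
#' two-sample t test with alternative "case deviations larger". For two
#' groups the squared t statistic equals the usual Levene ANOVA F, so this
#' is the signed version of the same test. Centering is by the group mean
#' (classic Levene) or median (Brown-Forsythe).
#'
#' @param residualsCase,residualsControl numeric vectors (n >= 3 each), or
#'   matrices with genes as rows for a vectorized per-gene test.
#' @param center \code{"mean"} (default, classic) or \code{"median"}.
#' @return one-sided p-value(s) in (0, 1]; exact ties with zero spread in
#'   both groups give p = 1 (degenerate, flagged via attribute).
#' @export
leveneOneSided <- function(residualsCase, residualsControl,
                           center = c("mean", "median")) {
    center <- match.arg(center)
    if (is.null(dim(residualsCase))) {
        residualsCase <- matrix(residualsCase, nrow = 1L)
        residualsControl <- matrix(residualsControl, nrow = 1L)
        scalarOut <- TRUE
    } else scalarOut <- FALSE
    n1 <- ncol(residualsCase)
    n0 <- ncol(residualsControl)
    if (n1 < 3L || n0 < 3L) stop("each group needs n >= 3")
    ctr <- function(m) {
        c0 <- if (center == "mean") rowMeans(m) else
            apply(m, 1L, stats::median)
        abs(m - c0)
    }
    d1 <- ctr(residualsCase)
    d0 <- ctr(residualsControl)
    m1 <- rowMeans(d1)
    m0 <- rowMeans(d0)
    ss1 <- rowSums((d1 - m1)^2)
    ss0 <- rowSums((d0 - m0)^2)
    df <- n1 + n0 - 2L
    sp <- sqrt((ss1 + ss0) / df)
    se <- sp * sqrt(1 / n1 + 1 / n0)
    tstat <- (m1 - m0) / se
    p <- pt(tstat, df, lower.tail = FALSE)
    degenerate <- se == 0
    p[degenerate & (m1 == m0)] <- 1
    p[degenerate & (m1 > m0)] <- 0 + .Machine$double.xmin
    p[degenerate & (m1 < m0)] <- 1
    if (scalarOut) {
        p <- as.numeric(p)
        attr(p, "degenerate") <- as.logical(degenerate)
    }
    p
}

#' Genome-wide variance comparison table
#'
#' Combines the raw-variance comparison with the residual-based one-sided
#' Levene test into one per-gene table, and reports the sign-test summary
#' (ties excluded).
#'
#' @param data a \code{SummarizedExperiment} with \code{group} colData, or
#'   a genes-by-samples matrix.
#' @param group group labels when \code{data} is a matrix.
#' @param covariates covariates for residualization (as in
#'   \code{\link{residualize}}); \code{NULL} uses the raw values, centered
#'   within group by the Levene statistic itself.
#' @param case,control group labels (defaults as in
#'   \code{\link{groupVariances}}).
#' @param center Levene centering, \code{"mean"} or \code{"median"}.
#' @return list with \code{table} (per-gene data.frame adding
#'   \code{leveneP}), \code{k} (genes with larger case variance), \code{n}
#'   (informative genes), \code{nTies}, and \code{signP}.
#' @export
varianceTable <- function(data, group = NULL, covariates = NULL,
                          case = NULL, control = NULL,
                          center = c("mean", "median")) {
    center <- match.arg(center)
    gm <- .groupMatrices(data, group)
    if (is.null(case)) case <- gm$levels[1L]
    if (is.null(control)) control <- setdiff(gm$levels, case)[1L]
    gv <- groupVariances(data, group, case, control)
    mat <- if (is.null(covariates)) gm$mat else residualize(data, covariates)
    ic <- gm$group == case
    ik <- gm$group == control
    lp <- leveneOneSided(mat[, ic, drop = FALSE], mat[, ik, drop = FALSE],
        center = center)
    gv$leveneP <- as.numeric(lp)
    k <- sum(gv$caseGreater, na.rm = TRUE)
    nTies <- sum(is.na(gv$caseGreater))
    n <- nrow(gv) - nTies
    list(table = gv, k = k, n = n, nTies = nTies,
        signP = if (n >= 1) signTest(k, n) else NA_real_)
}
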