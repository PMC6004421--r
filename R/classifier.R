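#' PCA of residuals with an explained-variance retention threshold
#'
#' Centered (unscaled by default) principal component analysis of a
#' genes-by-samples residual matrix; components whose individual
#' explained-variance fraction is at least \code{threshold} are retained,
#' in decreasing order.
#'
#' @param residuals genes-by-samples numeric matrix.
#' @param threshold minimum explained-variance fraction (default 0.01).
#' @param scale. standardize genes before PCA (default FALSE).
#' @return list with \code{scores} (samples x retained components),
#'   \code{explained} (all explained fractions), \code{retained} (count).
#' @export
pcaSelect <- function(residuals, threshold = 0.01, scale. = FALSE) {
    stopifnot(nrow(residuals) >= 2L, ncol(residuals) >= 2L)
    if (all(apply(residuals, 1L, sd) == 0))
        stop("constant residual matrix: PCA undefined")
    pc <- prcomp(t(residuals), center = TRUE, scale. = scale.)
    expl <- pc$sdev^2 / sum(pc$sdev^2)
    keep <- which(expl >= threshold)
    list(scores = pc$x[, keep, drop = FALSE], explained = expl,
        retained = length(keep))
}

#' Concordance index (area under the ROC curve)
#'
#' \eqn{P(\mathrm{score}_{case} > \mathrm{score}_{control}) + \frac12
#' P(tie)} over all case-control pairs, computed by the rank
#' (Mann-Whitney) formula with midranks, so ties count one half.
#'
#' @param scores numeric model scores.
#' @param labels binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the case).
#' @return C-index in [0, 1].
#' @export
cIndex <- function(scores, labels) {
    if (is.factor(labels)) labels <- labels == levels(labels)[2L]
    labels <- as.logical(labels)
    n1 <- sum(labels)
    n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic model of disease status from principal components
#'
#' Maximum-likelihood logistic regression with the retained components as
#' predictors and the group label as outcome; goodness of fit is reported
#' as the C-index of the fitted scores and a pseudo-R-squared
#' (Nagelkerke by default, McFadden optionally).
#'
#' @param components samples-by-components numeric matrix (e.g.,
#'   \code{pcaSelect(...)$scores}).
#' @param status binary outcome (see \code{\link{cIndex}}).
#' @param pseudoR2 \code{"nagelkerke"} (default) or \code{"mcfadden"}.
#' @return list with \code{nComponents}, \code{coefficients} (data.frame
#'   with estimate, z and p per component), \code{cIndex},
#'   \code{pseudoR2}, \code{pseudoR2Method}, \code{separationWarning}.
#' @export
logisticStatusFit <- function(components, status,
                              pseudoR2 = c("nagelkerke", "mcfadden")) {
    pseudoR2 <- match.arg(pseudoR2)
    if (is.factor(status)) status <- status == levels(status)[2L]
    y <- as.numeric(as.logical(status))
    if (length(unique(y)) < 2L) stop("both classes must be present")
    df <- as.data.frame(components)
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(y ~ ., data = cbind(y = y, df), family = binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
                sep <<- TRUE
                invokeRestart("muffleWarning")
            }
        })
    if (sep)
        warning("possible perfect separation: coefficients unreliable")
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1L],
        z = sm[, 3L], p = sm[, 4L], row.names = NULL)
    n <- length(y)
    dev0 <- fit$null.deviance
    dev1 <- fit$deviance
    r2 <- if (pseudoR2 == "nagelkerke") {
        (1 - exp((dev1 - dev0) / n)) / (1 - exp(-dev0 / n))
    } else 1 - dev1 / dev0
    list(nComponents = ncol(components),
        coefficients = co,
        cIndex = cIndex(fitted(fit), y == 1),
        pseudoR2 = r2, pseudoR2Method = pseudoR2,
        separationWarning = sep)
}

#' Pathway-gene covariance vs disease status report
#'
#' Convenience wrapper for the full classification stage: residualize the
#' pathway genes on covariates, PCA-select components explaining at least
#' the threshold fraction of variance, and fit the logistic status model.
#'
#' @param data a \code{SummarizedExperiment} with \code{group} colData.
#' @param genes gene symbols to analyze (rows of \code{data}).
#' @param covariates covariates for residualization (colData column names
#'   or a data.frame); \code{NULL} for none.
#' @param threshold PC retention threshold (default 0.01).
#' @param case label of the case group (default first group level).
#' @return list combining the \code{\link{pcaSelect}} and
#'   \code{\link{logisticStatusFit}} outputs.
#' @export
classifyStatus <- function(data, genes, covariates = NULL,
                           threshold = 0.01, case = NULL) {
    mat <- SummarizedExperiment::assay(data)
    miss <- setdiff(genes, rownames(mat))
    if (length(miss))
        stop("gene(s) absent from data: ", paste(miss, collapse = ", "))
    sub <- data[genes, ]
    resid <- if (is.null(covariates))
        SummarizedExperiment::assay(sub) else residualize(sub, covariates)
    grp <- SummarizedExperiment::colData(data)$group
    if (is.null(case)) case <- unique(as.character(grp))[1L]
    pca <- pcaSelect(resid, threshold = threshold)
    fit <- logisticStatusFit(pca$scores, as.character(grp) == case)
    c(list(explained = pca$explained, retained = pca$retained), fit)
}
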