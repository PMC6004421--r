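#' Model-selection criteria for the alternative-model search
#'
#' @param maxNonsignificant maximum number of non-significant
#'   control-group path coefficients a surviving model may have
#'   (default 3).
#' @param rmseaCeiling models with RMSEA at or above this value are
#'   discarded (default 0.2).
#' @param alpha two-sided significance level for a path coefficient on the
#'   control group (default 0.05).
#' @param cap maximum number of alternatives to enumerate (default 10000).
#' @return list of validated criteria.
#' @export
searchCriteria <- function(maxNonsignificant = 3L, rmseaCeiling = 0.2,
                           alpha = 0.05, cap = 10000L) {
    stopifnot(rmseaCeiling >= 0, alpha > 0, alpha < 1,
        maxNonsignificant >= 0, cap >= 1)
    list(maxNonsignificant = as.integer(maxNonsignificant),
        rmseaCeiling = rmseaCeiling, alpha = alpha, cap = as.integer(cap))
}

#' Significance star annotation
#'
#' \code{ns} for p >= 0.05, \code{*} for p < 0.05, \code{**} for p < 0.01,
#' \code{***} for p < 0.001 (the most extreme applicable label; strict
#' inequalities).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of labels.
#' @export
starAnnotation <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    out <- ifelse(p < 0.001, "***",
        ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
    out[is.na(p)] <- NA_character_
    out
}

#' Search the best alternative model for a pathway
#'
#' Enumerates all alternative single-gene models of the network, fits each
#' by multigroup SEM (covariate slopes shared across groups, structural
#' parameters group-specific), discards empirically non-identifiable fits,
#' fits with more than \code{maxNonsignificant} non-significant
#' control-group paths, and fits with RMSEA at or above the ceiling, then
#' selects the surviving model with the highest CFI (ties within 1e-6
#' break to lower RMSEA, then enumeration order).
#'
#' @param network a \linkS4class{PathwayNetwork} (at most 14 nodes).
#' @param groups named list of per-group datasets (see
#'   \code{\link{fitMultigroup}}); the control group is named by
#'   \code{control}.
#' @param covariates covariates passed to \code{\link{fitMultigroup}}.
#' @param criteria a \code{\link{searchCriteria}} list.
#' @param control name of the control group (default: second group).
#' @return a \code{BestModelReport} list: \code{pathway}, counts
#'   (\code{nGenerated}, \code{nIdentifiable}, \code{nSurviving}),
#'   \code{selected} (\linkS4class{ResolvedNetwork} or NULL),
#'   \code{selectedIndex}, \code{fit} (\linkS4class{MultigroupFit}),
#'   \code{indices}, \code{aic}, \code{bic}, \code{wald} (with star
#'   annotations), and \code{perAlternative} (per-alternative screening
#'   log with failure reasons).
#' @export
searchBestModel <- function(network, groups, covariates = NULL,
                            criteria = searchCriteria(), control = NULL) {
    stopifnot(is(network, "PathwayNetwork"))
    if (length(network@nodeIds) > 14L)
        stop("network exceeds the 14-node limit for SEM fitting")
    if (is.null(control)) control <- names(groups)[2L]
    if (!control %in% names(groups))
        stop("control group '", control, "' not among groups")
    alts <- enumerateAlternatives(network, cap = criteria$cap)
    log_ <- data.frame(index = seq_along(alts),
        genes = vapply(alts, function(a)
            paste(a@assignment, collapse = ","), character(1L)),
        identifiable = FALSE, nNonsignificant = NA_integer_,
        rmsea = NA_real_, cfi = NA_real_, status = "",
        stringsAsFactors = FALSE)
    fits <- vector("list", length(alts))
    for (i in seq_along(alts)) {
        fit <- tryCatch({
            model <- semFromNetwork(alts[[i]])
            fitMultigroup(model, groups, covariates = covariates)
        }, error = function(e) e)
        if (inherits(fit, "error")) {
            log_$status[i] <- paste("error:", conditionMessage(fit))
            next
        }
        fits[[i]] <- fit
        idOk <- checkIdentifiability(fit)
        if (!idOk) {
            log_$status[i] <- paste("non-identifiable:",
                paste(attr(idOk, "diagnostics"), collapse = "; "))
            next
        }
        log_$identifiable[i] <- TRUE
        ctrlFit <- fit@fits[[control]]
        pt <- fit@model@partable
        pathLabs <- pt$label[pt$free & pt$op == "~"]
        zc <- ctrlFit@estimates[pathLabs] / ctrlFit@se[pathLabs]
        pc <- 2 * pnorm(-abs(zc))
        nNon <- sum(pc >= criteria$alpha | !is.finite(pc))
        log_$nNonsignificant[i] <- nNon
        idx <- fitIndices(fit)
        log_$rmsea[i] <- idx$rmsea
        log_$cfi[i] <- idx$cfi
        if (nNon > criteria$maxNonsignificant) {
            log_$status[i] <- sprintf(
                "too many non-significant control paths (%d)", nNon)
        } else if (idx$rmsea >= criteria$rmseaCeiling) {
            log_$status[i] <- sprintf("RMSEA %.3f above ceiling",
                idx$rmsea)
        } else {
            log_$status[i] <- "surviving"
        }
    }
    surv <- which(log_$status == "surviving")
    report <- list(pathway = network@name, nGenerated = length(alts),
        nIdentifiable = sum(log_$identifiable),
        nSurviving = length(surv), perAlternative = log_,
        control = control, groups = names(groups))
    if (length(surv) == 0L) {
        report["selected"] <- list(NULL)
        report$selectedIndex <- NA_integer_
        return(report)
    }
    cfi <- log_$cfi[surv]
    best <- surv[cfi >= max(cfi) - 1e-6]
    if (length(best) > 1L) {
        rm_ <- log_$rmsea[best]
        best <- best[rm_ <= min(rm_) + 1e-9]
    }
    best <- best[1L]
    fit <- fits[[best]]
    wald <- fit@wald
    if (nrow(wald)) wald$stars <- starAnnotation(wald$p)
    report$selected <- alts[[best]]
    report$selectedIndex <- best
    report$fit <- fit
    report$indices <- fitIndices(fit)
    report$aic <- fit@aic
    report$bic <- fit@bic
    report$wald <- wald
    report
}

#' Which group is better explained by the selected model?
#'
#' Per-group AIC and BIC at the multigroup solution; lower values mean
#' the group's data are better explained by the pathway structure.
#'
#' @param report a \code{BestModelReport} from
#'   \code{\link{searchBestModel}} with a selected model.
#' @return list with \code{aic}, \code{bic}, \code{bestByAic},
#'   \code{bestByBic}.
#' @export
groupInformationComparison <- function(report) {
    if (is.null(report[["selected"]]))
        stop("no admissible model was selected for pathway '",
            report$pathway, "'")
    aic <- report$aic
    bic <- report$bic
    list(aic = aic, bic = bic,
        bestByAic = names(aic)[which.min(aic)],
        bestByBic = names(bic)[which.min(bic)])
}
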