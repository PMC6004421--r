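#' Structural equation model specification
#'
#' A linear structural model over observed and latent variables, stored as a
#' parameter table (one row per path coefficient, factor loading or
#' variance, with a free/fixed pattern fixed at construction). Internally
#' the model uses a single all-variable path matrix plus a diagonal
#' residual-covariance matrix, with selection down to the observed
#' variables; this is algebraically equivalent to the usual
#' B/Gamma/Lambda block formulation. Exogenous variables are modeled with
#' free variances and pairwise covariances fixed to zero; latent variables
#' are scaled by fixing their structural error variance to 1 (reference
#' scaling, mean 0).
#'
#' @slot variables all model variables (observed then latent).
#' @slot observed observed variable names (order defines the covariance
#'   matrix layout).
#' @slot latentVars latent variable names.
#' @slot partable data.frame with columns \code{lhs}, \code{op}
#'   (\code{"~"} regression, \code{"=~"} loading, \code{"~~"} variance),
#'   \code{rhs}, \code{free} (logical), \code{value} (fixed value; ignored
#'   for free rows), \code{label}.
#' @aliases SemModel
#' @export
setClass("SemModel",
    representation(
        variables = "character",
        observed = "character",
        latentVars = "character",
        partable = "data.frame"
    )
)

setValidity("SemModel", function(object) {
    msg <- character()
    pt <- object@partable
    need <- c("lhs", "op", "rhs", "free", "value", "label")
    if (!all(need %in% names(pt)))
        msg <- c(msg, "partable missing required columns")
    else {
        if (!all(pt$op %in% c("~", "=~", "~~")))
            msg <- c(msg, "unknown operator in partable")
        if (!all(c(pt$lhs, pt$rhs) %in% object@variables))
            msg <- c(msg, "partable refers to undeclared variables")
        vr <- pt$op == "~~"
        if (any(pt$lhs[vr] != pt$rhs[vr]))
            msg <- c(msg, "only diagonal (co)variances are representable")
        if (any(!pt$free[vr] & pt$value[vr] < 0))
            msg <- c(msg, "fixed variances must be >= 0")
    }
    if (anyDuplicated(object@variables))
        msg <- c(msg, "duplicate variable names")
    if (!all(object@latentVars %in% object@variables))
        msg <- c(msg, "latent variables must be declared variables")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SemModel", function(object) {
    pt <- object@partable
    cat(sprintf("SemModel: %d observed, %d latent; %d free parameters\n",
        length(object@observed), length(object@latentVars), sum(pt$free)))
    cat(sprintf("  paths: %d, loadings: %d, variances: %d (%d fixed)\n",
        sum(pt$op == "~"), sum(pt$op == "=~"), sum(pt$op == "~~"),
        sum(pt$op == "~~" & !pt$free)))
})

.ptRow <- function(lhs, op, rhs, free, value) {
    data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
        label = paste0(lhs, op, rhs), stringsAsFactors = FALSE)
}

#' Build a structural equation model
#'
#' Constructs a \linkS4class{SemModel} from a directed edge list. Every
#' variable that receives no structural path (and is not an indicator) is
#' exogenous with a free variance; every endogenous variable gets a free
#' structural error variance. Latent variables get a structural error
#' variance fixed to 1 (reference scaling); their indicators load with free
#' loadings, and a single-indicator measurement error is fixed to 0 (a
#' multi-indicator one is free).
#'
#' @param paths two-column matrix or data.frame of directed edges
#'   (source, target) between variables. Duplicated rows are kept (each
#'   becomes its own parameter), which renders the model non-identifiable
#'   and is caught at fit time.
#' @param latent character vector of latent variable names.
#' @param loadings two-column matrix (latent, indicator); required when any
#'   indicator measures a latent variable.
#' @param fixedVariances optional named numeric vector; the named
#'   variables' variances are fixed to the given values instead of free.
#' @param variables optional extra observed variables that carry no paths
#'   (free variance only); with \code{paths = NULL} this builds the
#'   independence model over them.
#' @return a \linkS4class{SemModel}.
#' @examples
#' m <- semModel(rbind(c("x", "y"), c("y", "z")))
#' impliedCovariance(m, c("y~x" = 0.8, "z~y" = 0.5, "x~~x" = 1,
#'     "y~~y" = 1, "z~~z" = 1))
#' @export
semModel <- function(paths = NULL, latent = character(), loadings = NULL,
                     fixedVariances = NULL, variables = NULL) {
    if (!is.null(paths) && length(paths)) {
        paths <- matrix(as.character(as.matrix(paths)), ncol = 2L)
    } else paths <- matrix(character(), ncol = 2L)
    if (!is.null(loadings) && length(loadings)) {
        loadings <- matrix(as.character(as.matrix(loadings)), ncol = 2L)
    } else loadings <- matrix(character(), ncol = 2L)
    indicators <- loadings[, 2L]
    vars <- unique(c(as.vector(t(paths)), latent, as.vector(t(loadings)),
        as.character(variables)))
    observed <- setdiff(vars, latent)
    vars <- c(observed, setdiff(latent, observed))

    rows <- list()
    for (i in seq_len(nrow(paths)))
        rows[[length(rows) + 1L]] <-
            .ptRow(paths[i, 2L], "~", paths[i, 1L], TRUE, NA_real_)
    for (i in seq_len(nrow(loadings)))
        rows[[length(rows) + 1L]] <-
            .ptRow(loadings[i, 1L], "=~", loadings[i, 2L], TRUE, NA_real_)
    nIndic <- table(loadings[, 1L])
    for (v in vars) {
        if (!is.null(fixedVariances) && v %in% names(fixedVariances)) {
            rows[[length(rows) + 1L]] <-
                .ptRow(v, "~~", v, FALSE, unname(fixedVariances[v]))
        } else if (v %in% latent) {
            # reference scaling: structural error variance fixed to 1
            rows[[length(rows) + 1L]] <- .ptRow(v, "~~", v, FALSE, 1)
        } else if (v %in% indicators) {
            lat <- loadings[match(v, loadings[, 2L]), 1L]
            free <- nIndic[[lat]] >= 2L
            rows[[length(rows) + 1L]] <-
                .ptRow(v, "~~", v, free, if (free) NA_real_ else 0)
        } else {
            rows[[length(rows) + 1L]] <- .ptRow(v, "~~", v, TRUE, NA_real_)
        }
    }
    pt <- do.call(rbind, rows)
    rownames(pt) <- NULL
    m <- new("SemModel", variables = vars, observed = observed,
        latentVars = setdiff(latent, observed), partable = pt)
    validObject(m)
    m
}

#' Build the SEM for a resolved pathway network
#'
#' Maps each non-latent node to its assigned gene (an observed variable)
#' and each latent node to a latent variable measured by its assigned gene.
#' Node-level edges become structural paths between the mapped variables.
#' Models with more than \code{maxNodes} nodes are rejected: larger
#' covariance structures are not reliably identifiable at the sample sizes
#' this workflow targets.
#'
#' @param resolved a \linkS4class{ResolvedNetwork}.
#' @param maxNodes hard node-count limit (default 14).
#' @return a \linkS4class{SemModel} whose observed variables are gene
#'   symbols.
#' @export
semFromNetwork <- function(resolved, maxNodes = 14L) {
    stopifnot(is(resolved, "ResolvedNetwork"))
    nNodes <- length(resolved@assignment)
    if (nNodes > maxNodes)
        stop(sprintf("network has %d nodes; models are limited to %d nodes",
            nNodes, maxNodes))
    lat <- names(resolved@assignment)[resolved@latent]
    varOf <- ifelse(names(resolved@assignment) %in% lat,
        names(resolved@assignment), resolved@assignment)
    names(varOf) <- names(resolved@assignment)
    if (anyDuplicated(varOf))
        stop("resolved network assigns the same gene to multiple nodes: ",
            paste(unique(varOf[duplicated(varOf)]), collapse = ", "))
    e <- resolved@edges
    paths <- if (nrow(e)) cbind(varOf[e[, 1L]], varOf[e[, 2L]]) else NULL
    loadings <- if (length(lat))
        cbind(lat, resolved@assignment[lat]) else NULL
    semModel(paths = paths, latent = lat, loadings = loadings)
}

#' Number of free parameters
#' @param model a \linkS4class{SemModel}.
#' @return integer.
#' @export
nFreeParams <- function(model) sum(model@partable$free)

#' Free-parameter labels
#' @param model a \linkS4class{SemModel}.
#' @return character vector in parameter-vector order.
#' @export
paramLabels <- function(model) model@partable$label[model@partable$free]

# Fill partable values from a named (or positional) theta over free rows.
.ptWithTheta <- function(model, theta) {
    pt <- model@partable
    free <- which(pt$free)
    if (!is.null(names(theta))) {
        miss <- setdiff(pt$label[free], names(theta))
        if (length(miss))
            stop("theta missing parameter(s): ", paste(miss, collapse = ", "))
        pt$value[free] <- theta[pt$label[free]]
    } else {
        if (length(theta) != length(free))
            stop("theta has wrong length: expected ", length(free))
        pt$value[free] <- theta
    }
    pt
}

# Assemble the all-variable path matrix A and diagonal residual covariance
# Psi from a filled partable. Duplicate rows accumulate.
.assembleRAM <- function(model, pt) {
    V <- model@variables
    nV <- length(V)
    A <- matrix(0, nV, nV, dimnames = list(V, V))
    Psi <- matrix(0, nV, nV, dimnames = list(V, V))
    for (i in seq_len(nrow(pt))) {
        v <- pt$value[i]
        switch(pt$op[i],
            "~" = { A[pt$lhs[i], pt$rhs[i]] <- A[pt$lhs[i], pt$rhs[i]] + v },
            "=~" = { A[pt$rhs[i], pt$lhs[i]] <- A[pt$rhs[i], pt$lhs[i]] + v },
            "~~" = { Psi[pt$lhs[i], pt$lhs[i]] <-
                Psi[pt$lhs[i], pt$lhs[i]] + v })
    }
    list(A = A, Psi = Psi)
}

#' Model-implied covariance matrix
#'
#' Assembles the covariance of the observed variables implied by the
#' structural parameters via the linear-structural reduction
#' \eqn{\Sigma = J (I-A)^{-1} \Psi (I-A)^{-T} J^{T}}, where \eqn{A} stacks
#' all paths and loadings over observed and latent variables, \eqn{\Psi}
#' is the diagonal residual covariance and \eqn{J} selects the observed
#' rows.
#'
#' @param model a \linkS4class{SemModel}.
#' @param theta parameter vector for the free parameters, either named by
#'   parameter label or positional in \code{paramLabels(model)} order.
#' @return symmetric covariance matrix over \code{model@observed}.
#' @export
setGeneric("impliedCovariance",
    function(model, theta) standardGeneric("impliedCovariance"))

#' @rdname impliedCovariance
setMethod("impliedCovariance", "SemModel", function(model, theta) {
    pt <- .ptWithTheta(model, theta)
    ram <- .assembleRAM(model, pt)
    nV <- length(model@variables)
    ImA <- diag(nV) - ram$A
    E <- tryCatch(solve(ImA), error = function(e)
        stop("singular (I - B): the structural system has no unique ",
            "reduced form at this parameter point"))
    Tfull <- E %*% ram$Psi %*% t(E)
    Sigma <- Tfull[model@observed, model@observed, drop = FALSE]
    (Sigma + t(Sigma)) / 2
})
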