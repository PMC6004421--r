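#' @useDynLib pathsem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats pbinom pchisq pnorm pt qnorm rbinom rnorm runif sd var
#'   cov glm binomial coef prcomp pf phyper setNames na.omit optim fitted
#'   model.matrix median cov2cor
#' @importFrom utils read.delim write.table head
NULL

#' Pathway network with complex (multi-gene) nodes
#'
#' A directed graph over pathway nodes. Each node carries one or more member
#' gene symbols; a node with two or more members (a paralog family or protein
#' complex) is called a \emph{complex node}. Latent nodes represent
#' unobserved pathway activity.
#'
#' @slot name pathway name.
#' @slot nodeIds character vector of unique node identifiers.
#' @slot members named list (by node id) of non-empty character vectors of
#'   member gene symbols.
#' @slot latent named logical vector (by node id).
#' @slot edges two-column character matrix of directed edges
#'   (source node id, target node id).
#'
#' @aliases PathwayNetwork
#' @export
setClass("PathwayNetwork",
    representation(
        name = "character",
        nodeIds = "character",
        members = "list",
        latent = "logical",
        edges = "matrix"
    )
)

setValidity("PathwayNetwork", function(object) {
    msg <- character()
    ids <- object@nodeIds
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate node id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!identical(sort(names(object@members)), sort(ids)))
        msg <- c(msg, "members must be named by node id")
    nm <- vapply(object@members, length, integer(1L))
    if (any(nm == 0L))
        msg <- c(msg, sprintf("node(s) with empty member list: %s",
            paste(names(nm)[nm == 0L], collapse = ", ")))
    if (!identical(sort(names(object@latent)), sort(ids)))
        msg <- c(msg, "latent flags must be named by node id")
    e <- object@edges
    if (ncol(e) != 2L)
        msg <- c(msg, "edges must be a two-column matrix")
    else if (nrow(e) > 0L) {
        bad <- !(e %in% ids)
        if (any(bad))
            msg <- c(msg, sprintf("edge endpoint(s) not declared as nodes: %s",
                paste(unique(e[bad]), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayNetwork
#'
#' @param name pathway name.
#' @param nodes named list mapping node id to a character vector of member
#'   gene symbols.
#' @param edges two-column character matrix (or list of length-2 vectors) of
#'   directed edges between node ids.
#' @param latent optional character vector of node ids to mark latent.
#' @return A \linkS4class{PathwayNetwork}.
#' @examples
#' net <- PathwayNetwork("toy",
#'     nodes = list(A = c("G1", "G2"), B = "G3"),
#'     edges = rbind(c("A", "B")))
#' countAlternatives(net)
#' @export
PathwayNetwork <- function(name, nodes, edges = NULL, latent = character()) {
    ids <- names(nodes)
    if (is.null(ids))
        stop("'nodes' must be a named list (node id -> members)")
    members <- lapply(nodes, as.character)
    if (is.null(edges) || length(edges) == 0L) {
        edges <- matrix(character(), ncol = 2L)
    } else if (is.list(edges)) {
        edges <- do.call(rbind, lapply(edges, as.character))
    }
    edges <- matrix(as.character(edges), ncol = 2L,
        dimnames = list(NULL, c("src", "dst")))
    lat <- setNames(ids %in% latent, ids)
    new("PathwayNetwork", name = as.character(name), nodeIds = ids,
        members = members, latent = lat, edges = edges)
}

setMethod("show", "PathwayNetwork", function(object) {
    nc <- sum(vapply(object@members, length, integer(1L)) >= 2L)
    cat(sprintf(
        "PathwayNetwork '%s': %d nodes (%d complex), %d edges, %d genes\n",
        object@name, length(object@nodeIds), nc, nrow(object@edges),
        length(uniqueGenes(object))))
    cat(sprintf("alternative single-gene models: %d\n",
        countAlternatives(object)))
})

#' @rdname PathwayNetwork-accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname PathwayNetwork-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname PathwayNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname PathwayNetwork-accessors
#' @export
setGeneric("nodeMembers", function(x, node) standardGeneric("nodeMembers"))

#' Accessors for PathwayNetwork
#'
#' @param x a \linkS4class{PathwayNetwork}.
#' @param node a node id.
#' @return \code{networkName}: the pathway name; \code{networkNodes}: node
#'   ids; \code{networkEdges}: two-column edge matrix; \code{nodeMembers}:
#'   member genes of one node (or the full named list when \code{node} is
#'   missing).
#' @name PathwayNetwork-accessors
NULL

#' @rdname PathwayNetwork-accessors
setMethod("networkName", "PathwayNetwork", function(x) x@name)
#' @rdname PathwayNetwork-accessors
setMethod("networkNodes", "PathwayNetwork", function(x) x@nodeIds)
#' @rdname PathwayNetwork-accessors
setMethod("networkEdges", "PathwayNetwork", function(x) x@edges)
#' @rdname PathwayNetwork-accessors
setMethod("nodeMembers", "PathwayNetwork", function(x, node) {
    if (missing(node)) return(x@members)
    if (!node %in% x@nodeIds) stop("unknown node id: ", node)
    x@members[[node]]
})

#' Resolved (single-gene-per-node) network
#'
#' One alternative model structure: every node of a parent
#' \linkS4class{PathwayNetwork} substituted with exactly one of its member
#' genes, inducing a gene-level edge list.
#'
#' @slot parent name of the parent network.
#' @slot assignment named character vector, node id -> chosen gene.
#' @slot latent named logical vector by node id.
#' @slot edges two-column character matrix of node-level edges (inherited).
#' @aliases ResolvedNetwork
#' @export
setClass("ResolvedNetwork",
    representation(
        parent = "character",
        assignment = "character",
        latent = "logical",
        edges = "matrix"
    )
)

setMethod("show", "ResolvedNetwork", function(object) {
    cat(sprintf("ResolvedNetwork (parent '%s'): %d nodes, %d edges\n",
        object@parent, length(object@assignment), nrow(object@edges)))
    cat(paste(names(object@assignment), "=", object@assignment,
        collapse = ", "), "\n")
})

#' Gene-level edges of a resolved network
#'
#' @param x a \linkS4class{ResolvedNetwork}.
#' @return two-column character matrix of edges relabeled node -> gene.
#' @export
resolvedEdges <- function(x) {
    stopifnot(is(x, "ResolvedNetwork"))
    e <- x@edges
    if (nrow(e) == 0L)
        return(matrix(character(), ncol = 2L,
            dimnames = list(NULL, c("src", "dst"))))
    matrix(x@assignment[e], ncol = 2L, dimnames = list(NULL, c("src", "dst")))
}

#' Number of alternative single-gene models
#'
#' The product over nodes of member counts: every complex node contributes a
#' factor equal to its family/complex size.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @return integer count of alternative models.
#' @export
setGeneric("countAlternatives",
    function(network) standardGeneric("countAlternatives"))

#' @rdname countAlternatives
setMethod("countAlternatives", "PathwayNetwork", function(network) {
    as.integer(prod(vapply(network@members, length, integer(1L))))
})

#' Enumerate all alternative single-gene models
#'
#' Expands the Cartesian product of member-gene substitutions over all
#' nodes, in deterministic lexicographic order of (node id, member index):
#' node ids are taken in their declared order and later nodes vary fastest.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param cap maximum number of alternatives allowed (guards runaway
#'   enumeration); default 10000.
#' @return list of \linkS4class{ResolvedNetwork}, of length
#'   \code{countAlternatives(network)}.
#' @export
setGeneric("enumerateAlternatives",
    function(network, cap = 10000L) standardGeneric("enumerateAlternatives"))

#' @rdname enumerateAlternatives
setMethod("enumerateAlternatives", "PathwayNetwork",
function(network, cap = 10000L) {
    total <- countAlternatives(network)
    if (total > cap)
        stop(sprintf(paste0("network '%s' has %d alternative models, more ",
            "than the cap (%d); raise 'cap' to enumerate anyway"),
            network@name, total, cap))
    ids <- network@nodeIds
    sizes <- vapply(network@members, length, integer(1L))[ids]
    # mixed-radix counter, last node varies fastest
    idx <- rep(1L, length(ids))
    out <- vector("list", total)
    for (k in seq_len(total)) {
        genes <- vapply(seq_along(ids),
            function(j) network@members[[ids[j]]][idx[j]], character(1L))
        out[[k]] <- new("ResolvedNetwork", parent = network@name,
            assignment = setNames(genes, ids), latent = network@latent[ids],
            edges = network@edges)
        j <- length(ids)
        while (j >= 1L) {
            idx[j] <- idx[j] + 1L
            if (idx[j] <= sizes[j]) break
            idx[j] <- 1L
            j <- j - 1L
        }
    }
    out
})

#' Union of member genes across networks
#'
#' @param networks a \linkS4class{PathwayNetwork} or a list of them.
#' @return sorted character vector of unique gene symbols.
#' @export
uniqueGenes <- function(networks) {
    if (is(networks, "PathwayNetwork")) networks <- list(networks)
    stopifnot(length(networks) >= 1L)
    sort(unique(unlist(lapply(networks, function(n) unlist(n@members)),
        use.names = FALSE)))
}

#' Read a pathway network from JSON
#'
#' Expected schema:
#' \code{{"name": ..., "nodes": [{"id", "members": [...], "latent": false}],
#' "edges": [["src","dst"], ...]}}.
#'
#' @param path path to a JSON network file.
#' @return a validated \linkS4class{PathwayNetwork}.
#' @export
loadNetwork <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (fld in c("name", "nodes"))
        if (is.null(obj[[fld]]))
            stop("network file missing required field '", fld, "': ", path)
    ids <- vapply(obj$nodes, function(n) {
        if (is.null(n$id)) stop("node without 'id' in ", path)
        as.character(n$id)
    }, character(1L))
    members <- lapply(obj$nodes, function(n) {
        m <- unlist(n$members)
        if (is.null(m) || length(m) == 0L)
            stop("node '", n$id, "' has an empty member list in ", path)
        as.character(m)
    })
    names(members) <- ids
    latent <- ids[vapply(obj$nodes, function(n) isTRUE(n$latent), logical(1L))]
    edges <- if (length(obj$edges))
        lapply(obj$edges, function(e) {
            e <- unlist(e)
            if (length(e) != 2L) stop("malformed edge in ", path)
            as.character(e)
        }) else NULL
    net <- PathwayNetwork(obj$name, setNames(members, ids), edges, latent)
    validObject(net)
    net
}

#' Write a pathway network to JSON
#'
#' Inverse of \code{\link{loadNetwork}}; \code{load -> write -> load} is the
#' identity on network structure.
#'
#' @param network a \linkS4class{PathwayNetwork}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeNetwork <- function(network, path) {
    stopifnot(is(network, "PathwayNetwork"))
    nodes <- lapply(network@nodeIds, function(id) list(
        id = jsonlite::unbox(id),
        members = as.list(network@members[[id]]),
        latent = jsonlite::unbox(unname(network@latent[id]))))
    edges <- if (nrow(network@edges))
        lapply(seq_len(nrow(network@edges)),
            function(i) as.list(network@edges[i, ])) else list()
    obj <- list(name = jsonlite::unbox(network@name), nodes = nodes,
        edges = edges)
    writeLines(jsonlite::toJSON(obj, pretty = TRUE), path)
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors of gene symbols; descriptions are
#'   kept in the \code{"description"} attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1L)) < 3L
    if (any(bad))
        stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, character(1L), 1L)
    attr(sets, "description") <- setNames(
        vapply(parts, `[`, character(1L), 2L), names(sets))
    sets
}

#' Bundled example pathway networks
#'
#' Returns the five reduced signaling-pathway networks shipped with the
#' package (serine biosynthesis, PI3K-Akt, MAPK, neurotrophin, focal
#' adhesion). Edge topologies are reconstructed from canonical KEGG
#' diagrams and marked as such in the files.
#'
#' @param name optional single network name (file base name); when missing,
#'   all bundled networks are returned as a named list.
#' @return a \linkS4class{PathwayNetwork} or named list of them.
#' @export
bundledNetworks <- function(name) {
    dir <- system.file("extdata", "networks", package = "pathsem")
    files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
    nets <- lapply(files, loadNetwork)
    names(nets) <- sub("\\.json$", "", basename(files))
    if (!missing(name)) {
        if (!name %in% names(nets))
            stop("no bundled network named '", name, "'")
        return(nets[[name]])
    }
    nets
}
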