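#' Read an expression matrix and sample metadata from TSV files
#'
#' Expression: genes as rows, first column the gene symbol, samples as
#' columns. Metadata: one row per sample with columns \code{sample_id},
#' \code{group}, \code{age}, \code{sex}, \code{batch} and optionally
#' \code{PC1}, \code{PC2} (computed from the expression matrix when
#' absent).
#'
#' @param expressionPath path to the expression TSV.
#' @param metadataPath path to the metadata TSV.
#' @return a \code{SummarizedExperiment} with covariates in colData.
#' @export
readExpressionTsv <- function(expressionPath, metadataPath) {
    expr <- read.delim(expressionPath, check.names = FALSE)
    genes <- expr[[1L]]
    mat <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(mat) <- genes
    meta <- read.delim(metadataPath, check.names = FALSE)
    need <- c("sample_id", "group", "age", "sex", "batch")
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata is missing required column(s): ",
            paste(miss, collapse = ", "))
    missSamp <- setdiff(colnames(mat), meta$sample_id)
    if (length(missSamp))
        stop("sample(s) missing from metadata: ",
            paste(head(missSamp, 5L), collapse = ", "))
    meta <- meta[match(colnames(mat), meta$sample_id), ]
    if (!all(c("PC1", "PC2") %in% colnames(meta))) {
        pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
        meta$PC1 <- pc$x[, 1L]
        meta$PC2 <- if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0
    }
    cd <- data.frame(group = as.character(meta$group), age = meta$age,
        sex = meta$sex, batch = factor(meta$batch),
        PC1 = meta$PC1, PC2 = meta$PC2, row.names = meta$sample_id)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = mat), colData = S4Vectors::DataFrame(cd))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: genome-wide variance comparison (raw-variance sign
#' test plus residual-based one-sided Levene tests); pathway enrichment by
#' four methods with per-method FDR adjustment, pathways significant in
#' any method merged into one selected set; PCA-logistic classification of
#' group status from the union of selected-pathway genes; and the
#' alternative-model SEM search per selected pathway, with DOT path
#' diagrams. Stage tables, a machine-readable JSON summary and a log are
#' written to the output directory.
#'
#' @param config list with elements: \code{data} (a
#'   \code{SummarizedExperiment}) or \code{expression}/\code{metadata}
#'   (TSV paths); \code{networks} (named list of
#'   \linkS4class{PathwayNetwork} or character paths to network JSON
#'   files); optional \code{geneSets} (GMT path); \code{case} and
#'   \code{control} group labels; \code{covariates} (colData columns,
#'   default \code{age, sex, PC1, PC2, batch}); thresholds
#'   \code{enrichmentFdr} (default 0.01) and \code{pcThreshold} (default
#'   0.01); \code{criteria} (\code{\link{searchCriteria}});
#'   \code{nTrials}, \code{nPermutations}; \code{seed}; \code{outDir}.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config) {
    t0 <- proc.time()[["elapsed"]]
    cfg <- config
    if (is.null(cfg$outDir)) stop("config$outDir is required")
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(cfg$outDir, "run.log")
    logLines <- character()
    note <- function(...) {
        msg <- sprintf(...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    fdrThr <- if (is.null(cfg$enrichmentFdr)) 0.01 else cfg$enrichmentFdr
    pcThr <- if (is.null(cfg$pcThreshold)) 0.01 else cfg$pcThreshold
    criteria <- if (is.null(cfg$criteria)) searchCriteria() else cfg$criteria
    covars <- if (is.null(cfg$covariates))
        c("age", "sex", "PC1", "PC2", "batch") else cfg$covariates
    nTrials <- if (is.null(cfg$nTrials)) 1e5L else as.integer(cfg$nTrials)
    nPerm <- if (is.null(cfg$nPermutations)) 1000L else
        as.integer(cfg$nPermutations)

    data <- if (!is.null(cfg$data)) cfg$data else
        readExpressionTsv(cfg$expression, cfg$metadata)
    grp <- as.character(SummarizedExperiment::colData(data)$group)
    case <- if (is.null(cfg$case)) unique(grp)[1L] else cfg$case
    control <- if (is.null(cfg$control))
        setdiff(unique(grp), case)[1L] else cfg$control
    networks <- cfg$networks
    if (is.character(networks)) {
        networks <- lapply(networks, loadNetwork)
        names(networks) <- vapply(networks, networkName, character(1L))
    }
    note("pipeline start: %d genes, %d samples (case=%s n=%d, control=%s n=%d)",
        nrow(data), ncol(data), case, sum(grp == case), control,
        sum(grp == control))

    summary <- list(
        package = as.character(utils::packageVersion("pathsem")),
        rVersion = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed, case = case, control = control,
        thresholds = list(enrichmentFdr = fdrThr, pcThreshold = pcThr,
            rmseaCeiling = criteria$rmseaCeiling,
            maxNonsignificant = criteria$maxNonsignificant))

    # ---- stage 1: variance -------------------------------------------
    vt <- varianceTable(data, covariates = covars, case = case,
        control = control)
    .writeTsv(vt$table, file.path(cfg$outDir, "variance.tsv"))
    note("variance: k=%d of n=%d genes with larger %s variance (sign p=%.3g)",
        vt$k, vt$n, case, vt$signP)
    summary$variance <- list(k = vt$k, n = vt$n, nTies = vt$nTies,
        signP = vt$signP)

    # ---- stage 2: enrichment -----------------------------------------
    indicator <- setNames(!is.na(vt$table$caseGreater) &
        vt$table$caseGreater %in% TRUE, vt$table$gene)
    genePv <- setNames(vt$table$leveneP, vt$table$gene)
    enr <- enrichmentAnalysis(networks, indicator, genePv,
        nTrials = nTrials, nPermutations = nPerm, seed = seed)
    .writeTsv(enr, file.path(cfg$outDir, "enrichment.tsv"))
    sel <- unique(enr$pathway[!is.na(enr$fdr) & enr$fdr < fdrThr])
    note("enrichment: %d of %d pathways selected at FDR < %g (%s)",
        length(sel), length(networks), fdrThr,
        if (length(sel)) paste(sel, collapse = ", ") else "none")
    summary$enrichment <- list(selected = as.list(sel),
        nPathways = length(networks))

    selNets <- networks[vapply(networks, networkName, character(1L))
        %in% sel]

    # ---- stage 3: classifier -----------------------------------------
    if (length(selNets)) {
        genes <- intersect(uniqueGenes(unname(selNets)), rownames(data))
        cls <- classifyStatus(data, genes, covariates = covars,
            threshold = pcThr, case = case)
        .writeTsv(cls$coefficients,
            file.path(cfg$outDir, "classifier.tsv"))
        note("classifier: %d genes, %d PCs retained, C-index=%.3f, R2=%.3f",
            length(genes), cls$retained, cls$cIndex, cls$pseudoR2)
        summary$classifier <- list(nGenes = length(genes),
            retained = cls$retained, cIndex = cls$cIndex,
            pseudoR2 = cls$pseudoR2, pseudoR2Method = cls$pseudoR2Method)
    } else {
        note("classifier: skipped (no pathway passed enrichment)")
        summary$classifier <- NULL
    }

    # ---- stage 4: model search ---------------------------------------
    groupsData <- splitByGroup(data)[c(case, control)]
    names(groupsData) <- c(case, control)
    searchSummaries <- list()
    for (nm in names(selNets)) {
        net <- selNets[[nm]]
        rep_ <- tryCatch(
            searchBestModel(net, groupsData, covariates = covars,
                criteria = criteria, control = control),
            error = function(e) e)
        if (inherits(rep_, "error")) {
            note("search[%s]: failed: %s", nm, conditionMessage(rep_))
            searchSummaries[[nm]] <- list(error = conditionMessage(rep_))
            next
        }
        .writeTsv(rep_$perAlternative,
            file.path(cfg$outDir, paste0("search_", gsub("\\W+", "_", nm),
                ".tsv")))
        if (!is.null(rep_[["selected"]])) {
            dot <- file.path(cfg$outDir,
                paste0("diagram_", gsub("\\W+", "_", nm), ".dot"))
            exportPathDiagram(rep_, dot)
            gi <- groupInformationComparison(rep_)
            note("search[%s]: %d/%d/%d generated/identifiable/surviving; best #%d CFI=%.3f RMSEA=%.3f; better-explained group (AIC): %s",
                nm, rep_$nGenerated, rep_$nIdentifiable, rep_$nSurviving,
                rep_$selectedIndex, rep_$indices$cfi, rep_$indices$rmsea,
                gi$bestByAic)
            searchSummaries[[nm]] <- list(
                nGenerated = rep_$nGenerated,
                nIdentifiable = rep_$nIdentifiable,
                nSurviving = rep_$nSurviving,
                selectedIndex = rep_$selectedIndex,
                selectedGenes = as.list(unname(
                    rep_[["selected"]]@assignment)),
                cfi = rep_$indices$cfi, rmsea = rep_$indices$rmsea,
                aic = as.list(rep_$aic), bic = as.list(rep_$bic),
                significantPaths = if (nrow(rep_$wald)) as.list(
                    rep_$wald$path[rep_$wald$testable &
                        rep_$wald$p < 0.05]) else list())
        } else {
            note("search[%s]: no admissible model", nm)
            searchSummaries[[nm]] <- list(nGenerated = rep_$nGenerated,
                nIdentifiable = rep_$nIdentifiable, nSurviving = 0L)
        }
    }
    summary$search <- searchSummaries
    summary$elapsedStages <- NULL

    json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 10,
        pretty = TRUE, null = "null")
    writeLines(json, file.path(cfg$outDir, "summary.json"))
    note("pipeline done in %.1f s", proc.time()[["elapsed"]] - t0)
    writeLines(logLines, logFile)
    invisible(summary)
}

#' Export a fitted path diagram in DOT format
#'
#' One labeled edge per structural path with three lines of text: the
#' control-group estimate (standard error), the case-group estimate, and
#' the significance annotation of the between-group difference.
#'
#' @param report a \code{BestModelReport} with a selected model.
#' @param path output .dot file path.
#' @return invisibly, \code{path}.
#' @export
exportPathDiagram <- function(report, path) {
    if (is.null(report[["selected"]]))
        stop("no selected model to draw for pathway '", report$pathway,
            "'")
    fit <- report$fit
    control <- report$control
    case <- setdiff(report$groups, control)[1L]
    iCtrl <- which(fit@groups == control)
    lines <- c("digraph pathway {",
        sprintf("  label=\"%s\";", report$pathway),
        "  node [shape=box];")
    vars <- fit@model@observed
    for (v in vars) lines <- c(lines, sprintf("  \"%s\";", v))
    wald <- report$wald
    if (nrow(wald)) {
        for (i in seq_len(nrow(wald))) {
            lhsrhs <- strsplit(wald$path[i], "~", fixed = TRUE)[[1L]]
            dst <- lhsrhs[1L]; src <- lhsrhs[2L]
            ctrlEst <- if (iCtrl == 1L) wald$est1[i] else wald$est2[i]
            ctrlSe <- if (iCtrl == 1L) wald$se1[i] else wald$se2[i]
            caseEst <- if (iCtrl == 1L) wald$est2[i] else wald$est1[i]
            star <- if (is.na(wald$p[i])) "ns" else
                starAnnotation(wald$p[i])
            lines <- c(lines, sprintf(
                "  \"%s\" -> \"%s\" [label=\"%s: %.2f (%.2f)\\n%s: %.2f\\n%s\"];",
                src, dst, control, ctrlEst, ctrlSe, case, caseEst, star))
        }
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
    invisible(path)
}
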