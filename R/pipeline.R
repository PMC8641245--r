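#' Default pipeline configuration
#'
#' Returns the full parameter block with its defaults: 5 pseudo-cells per
#' adjacent pair, 100 bootstrap runs, box fraction 0.1, significance cutoff
#' 0.01, hub fraction 0.2, conserved fraction 0.9, MCL inflation 2 with
#' minimum module size 3, average linkage, 100 random networks for the
#' permutation baseline and seed 42.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(mir = NULL, mrna = NULL, prior = NULL, validated = NULL,
                diseaseGenes = NULL, outdir = NULL,
                pseudoPerGap = 5L, bootstrapRuns = 100L, boxFraction = 0.1,
                alpha = 0.01, hubFraction = 0.2, conservedFraction = 0.9,
                mclInflation = 2, mclMinSize = 3L, linkage = "average",
                nRandom = 100L, nClusters = 3L, seed = 42L,
                keepPerRun = FALSE)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    .validateConfig(cfg)
    cfg
}

.validateConfig <- function(cfg) {
    with(cfg, {
        if (pseudoPerGap < 0) stop("config error: pseudoPerGap must be >= 0")
        if (bootstrapRuns < 1) stop("config error: bootstrapRuns must be >= 1")
        if (boxFraction <= 0 || boxFraction > 1)
            stop("config error: boxFraction must be in (0, 1]")
        if (alpha <= 0 || alpha >= 1)
            stop("config error: alpha must be in (0, 1)")
        if (hubFraction <= 0 || hubFraction > 1)
            stop("config error: hubFraction must be in (0, 1]")
        if (conservedFraction <= 0 || conservedFraction > 1)
            stop("config error: conservedFraction must be in (0, 1]")
        if (mclInflation <= 1) stop("config error: mclInflation must be > 1")
        if (!linkage %in% c("average", "single", "complete"))
            stop("config error: unknown linkage ", linkage)
    })
    invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are \code{\link{pipelineConfig}}
#'   parameters.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the full per-cell network inference workflow
#'
#' End-to-end orchestration: read and preprocess the matched matrices,
#' build the bootstrap ensemble of pseudo-cell-augmented datasets, infer
#' the per-cell networks, and run the downstream analytics (hubs,
#' conserved/rewired regulation, similarity matrices, hierarchical
#' clustering, crosstalk networks and their MCL modules, optional
#' reference-based evaluation and optional biclique modules with disease
#' enrichment). All tables are written under \code{outdir} together with a
#' machine-readable \code{summary.json} (which round-trips the effective
#' parameter block) and a plain-text log.
#'
#' @param config list from \code{\link{pipelineConfig}} /
#'   \code{\link{readPipelineConfig}}. \code{mir}, \code{mrna} and
#'   \code{prior} may be file paths or in-memory objects
#'   (\linkS4class{ExpressionMatrix} / \linkS4class{MatchedCoSeq} /
#'   \linkS4class{PairSet}); \code{outdir} is required.
#' @param data optional \linkS4class{MatchedCoSeq} overriding
#'   \code{config$mir}/\code{config$mrna}.
#' @param prior optional \linkS4class{PairSet} overriding
#'   \code{config$prior}.
#' @return invisibly, a list with the main in-memory results
#'   (\code{networks}, \code{conserved}, \code{similarity}, \code{clusters},
#'   \code{crosstalk}, \code{evaluation}, \code{modules}, \code{summary}).
#' @export
runPipeline <- function(config, data = NULL, prior = NULL) {
    .validateConfig(config)
    if (is.null(config$outdir)) stop("config error: 'outdir' is required")
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(config$outdir, "run.log")
    logf <- function(...) cat(sprintf(...), "\n", sep = "",
                              file = logFile, append = TRUE)
    cat("", file = logFile)
    logf("stage=config %s", jsonlite::toJSON(.serializableConfig(config),
                                             auto_unbox = TRUE))

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            logf("stage=%s status=error message=%s", name, conditionMessage(e))
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    data <- stage("input", {
        if (is.null(data)) {
            if (is(config$mir, "MatchedCoSeq")) config$mir
            else {
                mir <- if (is(config$mir, "ExpressionMatrix")) config$mir
                       else readExpressionMatrix(config$mir, "miRNA")
                mrna <- if (is(config$mrna, "ExpressionMatrix")) config$mrna
                        else readExpressionMatrix(config$mrna, "mRNA")
                preprocessMatched(mir, mrna)
            }
        } else data
    })
    prior <- stage("input", {
        if (is.null(prior)) {
            if (is(config$prior, "PairSet")) config$prior
            else if (is.null(config$prior))
                stop("config error: 'prior' is required")
            else readPairSet(config$prior, label = "prior")
        } else prior
    })
    m <- length(cellIds(data))
    logf("stage=input cells=%d mirnas=%d mrnas=%d prior=%d", m,
         nrow(exprValues(mirMatrix(data))),
         nrow(exprValues(mrnaMatrix(data))), length(prior))

    net <- stage("networks", {
        ens <- bootstrapEnsemble(data, q = config$pseudoPerGap,
                                 B = config$bootstrapRuns,
                                 seed = config$seed)
        buildCellNetworks(ens, prior, alpha = config$alpha,
                          boxFraction = config$boxFraction,
                          keepPerRun = config$keepPerRun)
    })
    writeCellNetworks(net, file.path(config$outdir, "networks"))
    edgeCounts <- colSums(net@pFinal < net@alpha)
    logf("stage=networks cells=%d testedPairs=%d edges=%s", m,
         nrow(net@pairs), paste(edgeCounts, collapse = ","))

    cons <- stage("downstream", {
        conservedAndRewired(net,
            conservedMinCells = ceiling(config$conservedFraction * m),
            hubFraction = config$hubFraction)
    })
    writePairSet(cons$conservedEdges,
                 file.path(config$outdir, "conserved_edges.tsv"))
    writePairSet(cons$rewiredEdges,
                 file.path(config$outdir, "rewired_edges.tsv"))
    writeLines(cons$conservedHubs,
               file.path(config$outdir, "conserved_hubs.txt"))
    writeLines(cons$rewiredHubs,
               file.path(config$outdir, "rewired_hubs.txt"))

    sims <- stage("downstream", list(
        interaction = similarityMatrix(net, "interaction"),
        hub = similarityMatrix(net, "hub", hubFraction = config$hubFraction)))
    for (mode in names(sims))
        utils::write.table(sims[[mode]],
            file.path(config$outdir, paste0("similarity_", mode, ".tsv")),
            sep = "\t", quote = FALSE)
    dist <- stage("downstream", expressionDistanceMatrix(data))
    utils::write.table(dist$normalized,
        file.path(config$outdir, "distance_normalized.tsv"),
        sep = "\t", quote = FALSE)

    nClusters <- min(config$nClusters, m)
    clusters <- stage("downstream", lapply(sims, hierarchicalClustering,
        nClusters = nClusters, linkage = config$linkage))
    labTab <- data.frame(cell = cellIds(data),
        interaction = clusters$interaction$labels[cellIds(data)],
        hub = clusters$hub$labels[cellIds(data)])
    utils::write.table(labTab, file.path(config$outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    crosstalk <- stage("downstream", lapply(sims, crosstalkNetwork))
    mcl <- list(); hubs <- list()
    for (mode in names(crosstalk)) {
        utils::write.table(crosstalk[[mode]]$edges,
            file.path(config$outdir, paste0("crosstalk_", mode, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        hubs[[mode]] <- tryCatch(
            hubCells(crosstalk[[mode]], config$hubFraction),
            warning = function(w) character(0))
        mcl[[mode]] <- stage("downstream",
            mclModules(crosstalk[[mode]], inflation = config$mclInflation,
                       minSize = config$mclMinSize))
    }

    evaluation <- NULL
    if (!is.null(config$validated)) {
        validated <- if (is(config$validated, "PairSet")) config$validated
                     else readPairSet(config$validated, label = "validated")
        evaluation <- stage("evaluate",
            evaluateAgainstReference(net, validated,
                                     nRandom = config$nRandom,
                                     seed = config$seed))
        utils::write.table(evaluation,
            file.path(config$outdir, "evaluation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }

    modules <- NULL
    if (!is.null(config$diseaseGenes)) {
        disease <- if (is.character(config$diseaseGenes)
                       && length(config$diseaseGenes) == 1L
                       && file.exists(config$diseaseGenes))
            readGeneList(config$diseaseGenes) else config$diseaseGenes
        background <- c(rownames(exprValues(mirMatrix(data))),
                        rownames(exprValues(mrnaMatrix(data))))
        bic <- stage("modules", maximalBicliques(cons$conservedEdges))
        modules <- stage("modules", enrichModules(bic, disease, background))
        jsonlite::write_json(
            list(modules = lapply(seq_along(bic), function(i)
                c(bic[[i]], as.list(modules[i, ])))),
            file.path(config$outdir, "modules.json"), auto_unbox = TRUE)
    }

    summary <- list(
        parameters = .serializableConfig(config),
        nCells = m,
        nTestedPairs = nrow(net@pairs),
        edgesPerCell = as.list(stats::setNames(as.integer(edgeCounts),
                                               names(edgeCounts))),
        nConservedEdges = length(cons$conservedEdges),
        nRewiredEdges = length(cons$rewiredEdges),
        conservedHubs = cons$conservedHubs,
        rewiredHubs = cons$rewiredHubs,
        similarityRange = lapply(sims, function(s)
            range(s[upper.tri(s)])),
        crosstalkEdges = lapply(crosstalk, function(x) nrow(x$edges)),
        hubCells = hubs,
        mclModules = lapply(mcl, function(x) x$modules))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logf("stage=done")
    invisible(list(networks = net, conserved = cons, similarity = sims,
                   distance = dist, clusters = clusters,
                   crosstalk = crosstalk, mcl = mcl,
                   evaluation = evaluation, modules = modules,
                   summary = summary))
}

# parameter block for the summary: input locations (which may be temp paths
# or in-memory objects) are excluded so identical runs give identical
# summaries; everything that shapes the computation is kept
.serializableConfig <- function(cfg) {
    cfg[setdiff(names(cfg),
                c("mir", "mrna", "prior", "validated", "diseaseGenes",
                  "outdir"))]
}
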