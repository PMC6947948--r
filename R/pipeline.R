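#' @include simulate.R consensus.R
NULL

#' Read a pipeline run configuration
#'
#' YAML or JSON file with the fields accepted by \code{\link{runPipeline}}:
#' an \code{inputs} block (paths for \code{immune}, \code{inflammation},
#' \code{disease}, \code{ppi}, \code{expression}, \code{labels},
#' optionally \code{probes} and \code{drugs}) or a \code{simulate} block of
#' \code{\link{simulationConfig}} arguments; a \code{stages} vector; a
#' \code{params} block; \code{seed}; and \code{outdir}.
#'
#' @param path config file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("cannot read config: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
}

.PIPELINE_STAGES <- c("network", "score", "clusters", "drugs")

#' Run the full triplet-dysregulation pipeline
#'
#' Orchestrates the stages in order — triplet network construction,
#' dysregulation scoring with permutation significance, core-cluster
#' extraction with consensus classification, drug overlay — writing each
#' stage's tables under \code{outdir} and returning a machine-readable run
#' report (parameters, seed, per-stage counts and a file manifest with row
#' counts). Re-running with an identical config and seed reproduces
#' byte-identical outputs. Later stages require earlier ones: disabling
#' \code{"score"} also disables \code{"clusters"} and \code{"drugs"}.
#'
#' @param config list as from \code{\link{readRunConfig}}, or a path to a
#'   YAML/JSON config file.
#' @return the run report, invisibly (also written to
#'   \code{outdir/run_report.json}).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    outdir <- config$outdir %||% stop("config needs an 'outdir'")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stages <- config$stages %||% .PIPELINE_STAGES
    stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
    p <- config$params %||% list()
    nPerm <- p$nPerm %||% 1000
    alpha <- p$alpha %||% 0.05
    test <- p$test %||% "student"
    penalty <- p$penalty %||% 2
    kMax <- p$kMax %||% 5
    topN <- p$topN %||% 4
    elbow <- p$elbow %||% 0.1
    nResamples <- p$nResamples %||% 100
    mode <- p$mode %||% "all"
    seed <- as.integer(config$seed %||% 1L)
    report <- list(seed = seed, stages = stages,
                   params = list(nPerm = nPerm, alpha = alpha, test = test,
                                 penalty = penalty, kMax = kMax,
                                 topN = topN, elbow = elbow,
                                 nResamples = nResamples, mode = mode),
                   counts = list(), manifest = list())
    note <- function(...) message(sprintf(...))

    emit <- function(name, path, nrows) {
        report$manifest[[name]] <<- list(path = path, rows = nrows)
    }

    ## ---- inputs ------------------------------------------------------
    if (!is.null(config$simulate)) {
        simCfg <- do.call(simulationConfig,
                          c(config$simulate,
                            if (is.null(config$simulate$seed))
                                list(seed = deriveSeed(seed, 11L))))
        sim <- simulateScenario(simCfg)
        catalog <- sim$catalog; graph <- sim$graph; se <- sim$expr
        drugTable <- sim$drugs
        note("simulated scenario: %d genes, %d samples",
             igraph::vcount(graph), ncol(se))
    } else {
        inp <- config$inputs %||% stop("config needs 'inputs' or 'simulate'")
        for (f in c("immune", "inflammation", "disease", "ppi",
                    "expression", "labels"))
            if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
                stop("stage 'inputs': missing file for '", f, "': ",
                     inp[[f]] %||% "<unset>")
        catalog <- c(readGeneRoles(inp$immune, "IMMUNE"),
                     readGeneRoles(inp$inflammation, "INFLAMMATION"),
                     readGeneRoles(inp$disease, "DISEASE"))
        graph <- readPPIEdges(inp$ppi, dialect = inp$dialect %||% "tsv")
        if (!is.null(inp$probes)) {
            raw <- readSeriesMatrix(inp$expression)
            ann <- readProbeAnnotation(inp$probes)
            se <- collapseProbes(raw, ann, readSampleLabels(inp$labels))
        } else {
            se <- readExpressionMatrix(inp$expression, inp$labels)
        }
        drugTable <- if (!is.null(inp$drugs)) readDrugTargets(inp$drugs)
                     else data.frame(drugId = character(),
                                     drugName = character(),
                                     gene = character())
    }
    report$counts$genesInCatalog <- length(catalog)
    report$counts$ppiEdges <- igraph::ecount(graph)

    ## ---- stage: network ----------------------------------------------
    if (!"network" %in% stages)
        stop("the 'network' stage is required by all later stages")
    ts <- enumerateTriplets(graph, catalog, mode = mode)
    net <- buildTripletNetwork(ts, catalog)
    report$counts$triplets <- length(ts)
    report$counts$networkNodes <- igraph::vcount(net)
    report$counts$networkEdges <- igraph::ecount(net)
    tsPath <- file.path(outdir, "triplets.tsv")
    writeTripletTable(ts, tsPath); emit("triplets", tsPath, length(ts))
    sifPath <- file.path(outdir, "triplet_network.sif")
    writeNetworkSIF(net, sifPath)
    emit("triplet_network_sif", sifPath, igraph::ecount(net))
    fit <- tryCatch(scaleFreeFit(net), error = function(e) NULL)
    if (!is.null(fit)) {
        report$counts$scaleFreeR2 <- fit$rSquared
        report$counts$scaleFreeSlope <- fit$slope
    }

    ## ---- stage: score -------------------------------------------------
    dys <- NULL
    if ("score" %in% stages && length(ts) > 0L) {
        scores <- permutationPValues(se, ts, nPerm = nPerm,
                                     seed = deriveSeed(seed, 23L),
                                     test = test)
        dys <- selectDysregulated(scores, catalog, alpha = alpha)
        report$counts$scoredTriplets <- nrow(scores)
        report$counts$dysregulatedTriplets <- nrow(records(dys))
        if (nrow(records(dys)) > 0L)
            report$counts$rankConcordancePct <-
                rankConcordance(scores, dys)
        scPath <- file.path(outdir, "triplet_scores.tsv")
        writeTripletTable(scores, scPath)
        emit("triplet_scores", scPath, nrow(scores))
        dysPath <- file.path(outdir, "dysregulated_network.sif")
        writeNetworkSIF(networkGraph(dys), dysPath)
        emit("dysregulated_network_sif", dysPath,
             igraph::ecount(networkGraph(dys)))
    }

    ## ---- stage: clusters ----------------------------------------------
    if ("clusters" %in% stages && !is.null(dys) &&
        igraph::vcount(networkGraph(dys)) > 0L) {
        clusters <- greedyCohesiveClusters(networkGraph(dys),
                                           penalty = penalty, topN = topN)
        report$counts$coreClusters <- nrow(clusters)
        clPath <- file.path(outdir, "core_clusters.tsv")
        write.table(
            data.frame(cluster = seq_len(nrow(clusters)),
                       size = clusters$size,
                       density = clusters$density,
                       cohesiveness = clusters$cohesiveness,
                       members = vapply(clusters$members, paste,
                                        character(1), collapse = ";")),
            clPath, sep = "\t", quote = FALSE, row.names = FALSE)
        emit("core_clusters", clPath, nrow(clusters))
        if (nrow(clusters) > 0L) {
            cl1 <- clusters$members[[1L]]
            present <- intersect(cl1, rownames(se))
            if (length(present) >= 1L && ncol(se) >= kMax + 1L) {
                rep1 <- consensusCluster(se, kMax = kMax,
                                         nResamples = nResamples,
                                         seed = deriveSeed(seed, 37L),
                                         elbow = elbow, genes = present)
                report$counts$consensusChosenK <- chosenK(rep1)
                assoc <- tryCatch(
                    clusterDiseaseAssociation(sampleAssignment(rep1), se),
                    error = function(e) NULL)
                if (!is.null(assoc)) {
                    report$counts$clusterChi2 <- assoc$chi2
                    report$counts$clusterChi2P <- assoc$p
                }
                cPaths <- writeConsensusReport(rep1, outdir,
                                               prefix = "cluster1_consensus")
                emit("consensus_report", cPaths[length(cPaths)],
                     length(sampleAssignment(rep1)))
            }
        }
    }

    ## ---- stage: drugs --------------------------------------------------
    if ("drugs" %in% stages && !is.null(dys) && nrow(drugTable) > 0L) {
        dnet <- buildDrugNetwork(dys, drugTable)
        ranking <- rankDrugsByDegree(dnet)
        report$counts$drugsInNetwork <- nrow(ranking)
        report$counts$drugNetworkNodes <- igraph::vcount(dnet)
        report$counts$drugNetworkEdges <- igraph::ecount(dnet)
        drPath <- file.path(outdir, "drug_ranking.tsv")
        writeDrugRanking(ranking, drPath)
        emit("drug_ranking", drPath, nrow(ranking))
        dgPath <- file.path(outdir, "drug_network.graphml")
        writeNetworkGraphML(dnet, dgPath)
        emit("drug_network_graphml", dgPath, igraph::ecount(dnet))
    }

    reportPath <- file.path(outdir, "run_report.json")
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
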