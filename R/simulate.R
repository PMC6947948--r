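#' @include drug-overlay.R
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic scenario generator. Defaults describe a
#' desk-scale case/control cohort with planted dysregulated triplets:
#' moderate mean shifts (in units of the within-group SD) plus a
#' correlation sign flip between groups, on a sparse background
#' interaction graph.
#'
#' @param nGenes total number of genes.
#' @param roleFractions named fractions of non-triangle genes given each
#'   role (\code{immune}, \code{inflammation}, \code{disease}); genes can
#'   stay role-free (background interactors).
#' @param multifunctionFraction fraction of role-carrying background genes
#'   given a second role, exercising multi-assignment enumeration.
#' @param nTrianglesPlanted number of planted dysregulated triplets.
#' @param nTrianglesNull number of planted null (undisturbed) triplets.
#' @param backgroundEdgeProb Erdos-Renyi probability for background edges.
#' @param nCase,nCtrl samples per group (>= 3).
#' @param effectMeanShift case-group mean shift of planted genes, in units
#'   of \code{noiseSd}.
#' @param rhoCase,rhoCtrl pairwise correlation of a planted triplet's genes
#'   in cases / of every triplet's genes in controls (compound symmetric;
#'   repaired to the nearest positive-definite matrix when needed).
#' @param noiseSd within-group standard deviation.
#' @param baselineMean baseline expression level.
#' @param nDrugs,targetsPerDrug drug-target table dimensions.
#' @param seed integer seed; the scenario is byte-reproducible under it.
#' @return A validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nGenes = 500,
                             roleFractions = c(immune = 0.4,
                                               inflammation = 0.2,
                                               disease = 0.15),
                             multifunctionFraction = 0.15,
                             nTrianglesPlanted = 30,
                             nTrianglesNull = 120,
                             backgroundEdgeProb = 0.005,
                             nCase = 20, nCtrl = 20,
                             effectMeanShift = 1.5,
                             rhoCase = 0.6, rhoCtrl = -0.6,
                             noiseSd = 1, baselineMean = 8,
                             nDrugs = 20, targetsPerDrug = 3,
                             seed = 1L) {
    cfg <- list(nGenes = nGenes, roleFractions = roleFractions,
                multifunctionFraction = multifunctionFraction,
                nTrianglesPlanted = nTrianglesPlanted,
                nTrianglesNull = nTrianglesNull,
                backgroundEdgeProb = backgroundEdgeProb,
                nCase = nCase, nCtrl = nCtrl,
                effectMeanShift = effectMeanShift,
                rhoCase = rhoCase, rhoCtrl = rhoCtrl,
                noiseSd = noiseSd, baselineMean = baselineMean,
                nDrugs = nDrugs, targetsPerDrug = targetsPerDrug,
                seed = as.integer(seed))
    probs <- c(roleFractions, multifunctionFraction, backgroundEdgeProb)
    if (any(probs < 0 | probs > 1))
        stop("fractions and probabilities must lie in [0,1]")
    if (abs(rhoCase) >= 1 || abs(rhoCtrl) >= 1)
        stop("|rho| must be < 1")
    if (nCase < 3 || nCtrl < 3) stop("need >= 3 samples per group")
    nTriGenes <- 3 * (nTrianglesPlanted + nTrianglesNull)
    if (nGenes < nTriGenes)
        stop("nGenes too small for the requested triangles (need >= ",
             nTriGenes, ")")
    cfg
}

## Compound-symmetric 3x3 correlation, repaired to nearest PD when needed.
tripletCorrelation <- function(rho) {
    R <- matrix(rho, 3, 3); diag(R) <- 1
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
        R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    R
}

#' Simulate a full synthetic scenario with ground truth
#'
#' Generates a role catalog, an interaction graph containing planted
#' cross-role triangles (one gene per role each) over an Erdos-Renyi
#' background, a two-group expression matrix, a drug-target table and the
#' planted truth. Null triplets draw from the same trivariate normal in
#' both groups (mean \code{baselineMean}, correlation \code{rhoCtrl});
#' planted triplets shift the case-group means by
#' \code{effectMeanShift * noiseSd} and switch the case-group correlation
#' to \code{rhoCase}. Genes outside triangles are independent noise.
#'
#' @param config a \code{\link{simulationConfig}} list.
#' @return list with \code{catalog}, \code{graph}, \code{expr}
#'   (\code{SummarizedExperiment}), \code{drugs}, and \code{truth}
#'   (list of \code{planted} / \code{null} \linkS4class{TripletSet}s).
#' @export
simulateScenario <- function(config = simulationConfig()) {
    set.seed(config$seed)
    nTri <- config$nTrianglesPlanted + config$nTrianglesNull
    geneNames <- sprintf("G%04d", seq_len(config$nGenes))
    triGenes <- matrix(geneNames[seq_len(3 * nTri)], ncol = 3,
                       byrow = TRUE)  # columns: immune, inflammation, disease
    bgGenes <- geneNames[-seq_len(3 * nTri)]

    ## --- role catalog -------------------------------------------------
    syms <- c(triGenes[, 1], triGenes[, 2], triGenes[, 3])
    roles <- c(rep("IMMUNE", nTri), rep("INFLAMMATION", nTri),
               rep("DISEASE", nTri))
    rf <- config$roleFractions
    for (role in names(rf)) {
        pick <- bgGenes[stats::runif(length(bgGenes)) < rf[[role]]]
        if (length(pick)) {
            syms <- c(syms, pick)
            roles <- c(roles, rep(toupper(role), length(pick)))
        }
    }
    catalog <- GeneRoleCatalog(syms, roles)
    ## second role for a fraction of role-carrying background genes
    bgInCat <- intersect(bgGenes, genes(catalog))
    bgInCat <- bgInCat[vapply(bgInCat, function(g)
        length(rolesOf(catalog, g)) < 3L, logical(1))]
    multi <- bgInCat[stats::runif(length(bgInCat)) <
                     config$multifunctionFraction]
    if (length(multi)) {
        extra <- vapply(multi, function(g) {
            free <- setdiff(.ROLES, rolesOf(catalog, g))
            free[sample.int(length(free), 1L)]
        }, character(1))
        catalog <- c(catalog, GeneRoleCatalog(multi, extra))
    }

    ## --- interaction graph -------------------------------------------
    triEdges <- rbind(cbind(triGenes[, 1], triGenes[, 2]),
                      cbind(triGenes[, 1], triGenes[, 3]),
                      cbind(triGenes[, 2], triGenes[, 3]))
    bg <- igraph::sample_gnp(config$nGenes, config$backgroundEdgeProb)
    igraph::V(bg)$name <- geneNames
    bgEdges <- igraph::as_edgelist(bg)
    graph <- edgesFromPairs(c(triEdges[, 1], bgEdges[, 1]),
                            c(triEdges[, 2], bgEdges[, 2]))
    iso <- setdiff(geneNames, igraph::V(graph)$name)
    if (length(iso)) graph <- igraph::add_vertices(graph, length(iso),
                                                   name = iso)

    ## --- expression ---------------------------------------------------
    n1 <- config$nCase; n2 <- config$nCtrl
    samples <- c(sprintf("CASE%03d", seq_len(n1)),
                 sprintf("CTRL%03d", seq_len(n2)))
    expr <- matrix(stats::rnorm(config$nGenes * (n1 + n2),
                                mean = config$baselineMean,
                                sd = config$noiseSd),
                   nrow = config$nGenes,
                   dimnames = list(geneNames, samples))
    Rctrl <- tripletCorrelation(config$rhoCtrl)
    Rcase <- tripletCorrelation(config$rhoCase)
    sd <- config$noiseSd
    for (t in seq_len(nTri)) {
        planted <- t <= config$nTrianglesPlanted
        gset <- triGenes[t, ]
        muCase <- rep(config$baselineMean, 3) +
            if (planted) config$effectMeanShift * sd else 0
        Rc <- if (planted) Rcase else Rctrl
        expr[gset, seq_len(n1)] <-
            t(MASS::mvrnorm(n1, muCase, sd^2 * Rc))
        expr[gset, n1 + seq_len(n2)] <-
            t(MASS::mvrnorm(n2, rep(config$baselineMean, 3), sd^2 * Rctrl))
    }
    labels <- stats::setNames(c(rep("CASE", n1), rep("CONTROL", n2)),
                              samples)
    se <- makeExpressionSet(expr, labels)

    ## --- drugs ---------------------------------------------------------
    drugs <- if (config$nDrugs > 0) {
        ids <- sprintf("DR%04d", seq_len(config$nDrugs))
        data.frame(
            drugId = rep(ids, each = config$targetsPerDrug),
            drugName = rep(paste0("Drug_", seq_len(config$nDrugs)),
                           each = config$targetsPerDrug),
            gene = unlist(lapply(seq_len(config$nDrugs), function(i)
                sample(geneNames, config$targetsPerDrug))),
            stringsAsFactors = FALSE)
    } else data.frame(drugId = character(), drugName = character(),
                      gene = character(), stringsAsFactors = FALSE)

    planted <- seq_len(config$nTrianglesPlanted)
    nullIdx <- setdiff(seq_len(nTri), planted)
    list(catalog = catalog, graph = graph, expr = se, drugs = drugs,
         truth = list(
             planted = TripletSet(triGenes[planted, 1],
                                  triGenes[planted, 2],
                                  triGenes[planted, 3]),
             null = TripletSet(triGenes[nullIdx, 1],
                               triGenes[nullIdx, 2],
                               triGenes[nullIdx, 3])),
         config = config)
}

#' Recovery power and false-positive rate against planted truth
#'
#' @param scores score \code{DataFrame} with \code{permP} (from
#'   \code{\link{permutationPValues}}).
#' @param truth the \code{truth} element of a simulated scenario.
#' @param alpha significance threshold.
#' @return list with \code{power} (fraction of planted triplets recovered
#'   at \code{permP < alpha}) and \code{fpr} (fraction of null triplets
#'   called significant).
#' @export
empiricalPower <- function(scores, truth, alpha = 0.05) {
    if (length(truth$planted) + length(truth$null) == 0L)
        stop("empty truth")
    key <- function(d) paste(d$immune, d$inflammation, d$disease,
                             sep = "\r")
    sig <- key(scores)[scores$permP < alpha]
    rateIn <- function(ts) {
        if (length(ts) == 0L) return(NA_real_)
        mean(key(triplets(ts)) %in% sig)
    }
    list(power = rateIn(truth$planted), fpr = rateIn(truth$null))
}

#' Write a simulated scenario as the pipeline's input files
#'
#' Emits exactly the formats the readers consume: one role TSV per role,
#' an edge-list TSV, an expression TSV, a labels TSV and a drug-target
#' TSV.
#'
#' @param sim result of \code{\link{simulateScenario}}.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
writeScenario <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
        immune = file.path(dir, "genes_immune.tsv"),
        inflammation = file.path(dir, "genes_inflammation.tsv"),
        disease = file.path(dir, "genes_disease.tsv"),
        ppi = file.path(dir, "ppi_edges.tsv"),
        expression = file.path(dir, "expression.tsv"),
        labels = file.path(dir, "labels.tsv"),
        drugs = file.path(dir, "drug_targets.tsv"))
    rl <- geneRoles(sim$catalog)
    for (role in c("IMMUNE", "INFLAMMATION", "DISEASE")) {
        syms <- names(rl)[vapply(rl, function(r) role %in% r, logical(1))]
        writeLines(syms, paths[[tolower(role)]])
    }
    writeEdgeList(sim$graph, paths$ppi)
    m <- SummarizedExperiment::assay(sim$expr, "expr")
    write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                paths$expression, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cond <- SummarizedExperiment::colData(sim$expr)$condition
    write.table(data.frame(colnames(m), tolower(as.character(cond))),
                paths$labels, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(data.frame(drug_id = sim$drugs$drugId,
                           drug_name = sim$drugs$drugName,
                           gene_symbol = sim$drugs$gene),
                paths$drugs, sep = "\t", quote = FALSE, row.names = FALSE)
    paths
}
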