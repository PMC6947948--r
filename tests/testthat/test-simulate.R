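test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(rhoCase = 1.2), "rho")
    expect_error(simulationConfig(nCase = 2), "samples per group")
    expect_error(simulationConfig(backgroundEdgeProb = 1.5), "probabilities")
    expect_error(simulationConfig(nGenes = 10, nTrianglesPlanted = 5,
                                  nTrianglesNull = 5), "too small")
})

test_that("the same seed reproduces the scenario byte for byte", {
    cfg <- simulationConfig(nGenes = 80, nTrianglesPlanted = 2,
                            nTrianglesNull = 5, seed = 99)
    a <- simulateScenario(cfg)
    b <- simulateScenario(cfg)
    expect_identical(SummarizedExperiment::assay(a$expr, "expr"),
                     SummarizedExperiment::assay(b$expr, "expr"))
    expect_identical(geneRoles(a$catalog), geneRoles(b$catalog))
    expect_identical(igraph::as_edgelist(a$graph),
                     igraph::as_edgelist(b$graph))
    expect_identical(a$drugs, b$drugs)
})

test_that("planted triangles exist in the graph with one gene per role", {
    sim <- tinyScenario(seed = 61, nPlanted = 4, nNull = 6)
    tdf <- rbind(triplets(sim$truth$planted), triplets(sim$truth$null))
    for (i in seq_len(nrow(tdf))) {
        g3 <- unlist(tdf[i, ])
        expect_true(all(g3 %in% igraph::V(sim$graph)$name))
        sub <- igraph::induced_subgraph(sim$graph, g3)
        expect_equal(igraph::ecount(sub), 3L)   # full triangle
        expect_true("IMMUNE" %in% geneRoles(sim$catalog)[[g3[1]]])
        expect_true("INFLAMMATION" %in% geneRoles(sim$catalog)[[g3[2]]])
        expect_true("DISEASE" %in% geneRoles(sim$catalog)[[g3[3]]])
    }
    ## planted and null truths are disjoint
    key <- function(d) paste(d$immune, d$inflammation, d$disease)
    expect_length(intersect(key(triplets(sim$truth$planted)),
                            key(triplets(sim$truth$null))), 0)
})

test_that("group-wise moments converge to the configured values", {
    cfg <- simulationConfig(nGenes = 12, nTrianglesPlanted = 1,
                            nTrianglesNull = 1, backgroundEdgeProb = 0,
                            nCase = 500, nCtrl = 500,
                            effectMeanShift = 1.5, rhoCase = 0.6,
                            rhoCtrl = -0.6, seed = 71)
    sim <- simulateScenario(cfg)
    m <- SummarizedExperiment::assay(sim$expr, "expr")
    caseIdx <- 1:500; ctrlIdx <- 501:1000
    p <- unlist(triplets(sim$truth$planted))
    ## means: baseline 8 shifted by 1.5 SD in cases only
    expect_equal(unname(rowMeans(m[p, caseIdx])), rep(9.5, 3),
                 tolerance = 0.15)
    expect_equal(unname(rowMeans(m[p, ctrlIdx])), rep(8, 3),
                 tolerance = 0.15)
    ## case correlations near rhoCase
    cc <- cor(t(m[p, caseIdx]))
    expect_equal(mean(cc[upper.tri(cc)]), 0.6, tolerance = 0.15)
    ## control correlations near the PD-repaired rhoCtrl (about -0.5)
    cn <- cor(t(m[p, ctrlIdx]))
    expect_lt(mean(cn[upper.tri(cn)]), -0.35)
    ## null triplet: identical distribution in both groups
    nn <- unlist(triplets(sim$truth$null))
    expect_equal(unname(rowMeans(m[nn, caseIdx])),
                 unname(rowMeans(m[nn, ctrlIdx])), tolerance = 0.2)
})

test_that("written scenario files feed the readers end to end", {
    sim <- tinyScenario(seed = 81, nPlanted = 1, nNull = 4)
    dir <- withr::local_tempdir()
    paths <- writeScenario(sim, dir)
    expect_true(all(file.exists(unlist(paths))))
    catalog <- c(readGeneRoles(paths$immune, "IMMUNE"),
                 readGeneRoles(paths$inflammation, "INFLAMMATION"),
                 readGeneRoles(paths$disease, "DISEASE"))
    expect_identical(geneRoles(catalog), geneRoles(sim$catalog))
    g <- readPPIEdges(paths$ppi)
    expect_equal(igraph::ecount(g), igraph::ecount(sim$graph))
    se <- readExpressionMatrix(paths$expression, paths$labels)
    expect_equal(SummarizedExperiment::assay(se, "expr"),
                 SummarizedExperiment::assay(sim$expr, "expr"),
                 tolerance = 1e-8)
    dt <- readDrugTargets(paths$drugs)
    expect_setequal(unique(dt$drugId), unique(sim$drugs$drugId))
})

test_that("empirical power and false-positive rate count truth recovery", {
    sc <- S4Vectors::DataFrame(immune = c("A", "D"),
                               inflammation = c("B", "E"),
                               disease = c("C", "F"),
                               permP = c(0.01, 0.5))
    truth <- list(planted = TripletSet("A", "B", "C"),
                  null = TripletSet("D", "E", "F"))
    ep <- empiricalPower(sc, truth, alpha = 0.05)
    expect_equal(ep$power, 1)
    expect_equal(ep$fpr, 0)
    ## alpha = 0: nothing passes (add-one keeps p > 0)
    ep0 <- empiricalPower(sc, truth, alpha = 0)
    expect_equal(ep0$power, 0)
    expect_equal(ep0$fpr, 0)
    expect_error(empiricalPower(sc, list(planted = TripletSet(),
                                         null = TripletSet())), "empty")
})
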