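test_that("role lists read, merge by union, and deduplicate", {
    f <- withr::local_tempfile(lines = c("JAK3", "IL4R"))
    cat1 <- readGeneRoles(f, "IMMUNE")
    expect_setequal(genes(cat1), c("JAK3", "IL4R"))
    expect_true(all(vapply(geneRoles(cat1), identical, logical(1),
                           "IMMUNE")))

    f2 <- withr::local_tempfile(lines = c("A", "B"))
    f3 <- withr::local_tempfile(lines = c("B", "C", "C"))
    merged <- c(readGeneRoles(f2, "IMMUNE"),
                readGeneRoles(f3, "INFLAMMATION"))
    expect_equal(geneRoles(merged)$B, c("IMMUNE", "INFLAMMATION"))
    expect_equal(sum(genes(merged) == "C"), 1L)

    ## merge is commutative and idempotent
    a <- GeneRoleCatalog(c("X", "Y"), c("IMMUNE", "DISEASE"))
    b <- GeneRoleCatalog(c("Y", "Z"), c("INFLAMMATION", "DISEASE"))
    expect_equal(geneRoles(c(a, b)), geneRoles(c(b, a)))
    expect_equal(geneRoles(c(a, a)), geneRoles(a))

    empty <- withr::local_tempfile(lines = character())
    expect_error(readGeneRoles(empty, "IMMUNE"), "empty")
})

test_that("GMT role files contribute all member genes", {
    f <- withr::local_tempfile(
        lines = c("setA\tdesc\tG1\tG2", "setB\tdesc\tG2\tG3", "bad"))
    expect_warning(catg <- readGeneRoles(f, "DISEASE", format = "gmt"),
                   "malformed")
    expect_setequal(genes(catg), c("G1", "G2", "G3"))
})

test_that("PPI edge lists become simple undirected graphs", {
    f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA"))
    expect_message(g <- readPPIEdges(f), "dropped")
    expect_equal(igraph::vcount(g), 2L)
    expect_equal(igraph::ecount(g), 1L)

    f2 <- withr::local_tempfile(lines = character())
    g2 <- readPPIEdges(f2)
    expect_equal(igraph::vcount(g2), 0L)
    expect_equal(igraph::ecount(g2), 0L)

    f3 <- withr::local_tempfile(lines = c("A\tB", "B\tC", "A\tC"))
    g3 <- readPPIEdges(f3)
    expect_equal(igraph::vcount(g3), 3L)
    expect_equal(igraph::ecount(g3), 3L)

    ## HPRD flat dialect: symbols in columns 1 and 4
    f4 <- withr::local_tempfile(
        lines = c("ALDH1A1\t00001\tNP_1\tJAK3\t00002\tNP_2\tin vivo"))
    g4 <- readPPIEdges(f4, dialect = "hprd")
    expect_setequal(igraph::V(g4)$name, c("ALDH1A1", "JAK3"))
})

test_that("edge-list TSV round-trips a graph", {
    g <- randomGraph(15, 0.2)
    f <- withr::local_tempfile()
    writeEdgeList(g, f)
    g2 <- readPPIEdges(f)
    expect_setequal(igraph::V(g2)$name,
                    igraph::V(g)$name[igraph::degree(g) > 0])
    el <- function(gr) {
        e <- igraph::as_edgelist(gr)
        sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    }
    expect_equal(el(g2), el(g))
})

test_that("probe collapsing averages per gene and is order-invariant", {
    raw <- matrix(c(1, 3, 3, 5), nrow = 2, byrow = TRUE,
                  dimnames = list(c("p1", "p2"), c("s1", "s2")))
    ann <- data.frame(probe = c("p1", "p2"), symbol = c("G", "G"))
    out <- collapseProbes(raw, ann)
    expect_equal(unname(out["G", ]), c(2, 4))

    ## single-probe gene copied unchanged; unmapped probes dropped
    raw2 <- matrix(seq_len(20), nrow = 10,
                   dimnames = list(paste0("p", 1:10), c("s1", "s2")))
    ann2 <- data.frame(probe = paste0("p", 1:10),
                       symbol = rep(c("A", "B", "C", "D", ""), each = 2))
    out2 <- collapseProbes(raw2, ann2)
    expect_equal(nrow(out2), 4L)

    ## row-order invariance
    shuffled <- raw2[sample(nrow(raw2)), ]
    expect_equal(collapseProbes(shuffled, ann2), out2)

    expect_error(collapseProbes(raw, data.frame(probe = "zz",
                                                symbol = "G")),
                 "no probe maps")
})

test_that("series-matrix layout reads through the header block", {
    lines <- c("!Series_title\tfoo", "!Series_geo_accession\tGSE0",
               "!series_matrix_table_begin",
               "ID_REF\tS1\tS2", "p1\t1.5\t2.5", "p2\t3\t4",
               "!series_matrix_table_end")
    f <- withr::local_tempfile(lines = lines)
    m <- readSeriesMatrix(f)
    expect_equal(dim(m), c(2L, 2L))
    expect_equal(m["p1", "S2"], 2.5)
})

test_that("drug-target tables deduplicate and skip empty symbols", {
    f <- withr::local_tempfile(lines = c(
        "drug_id\tdrug_name\tgene_symbol",
        "DB1\tTamoxifen\tPRKCA", "DB1\tTamoxifen\tPRKCA",
        "DB2\tBosutinib\tPRKCA", "DB3\tNone\t"))
    expect_warning(dt <- readDrugTargets(f), "skipped")
    expect_equal(nrow(dt), 2L)
    expect_setequal(dt$drugId, c("DB1", "DB2"))

    f2 <- withr::local_tempfile(lines = c("drug_id\tgene_symbol",
                                          "DB1\tPRKCA"))
    expect_error(readDrugTargets(f2), "columns")
})

test_that("expression matrices join labels into a SummarizedExperiment", {
    m <- matrix(rnorm(6), 2, 3,
                dimnames = list(c("G1", "g2 "), c("s1", "s2", "s3")))
    se <- makeExpressionSet(m, c(s1 = "case", s2 = "control",
                                 s3 = "case"))
    expect_s4_class(se, "SummarizedExperiment")
    expect_equal(as.character(SummarizedExperiment::colData(se)$condition),
                 c("CASE", "CONTROL", "CASE"))
    expect_error(makeExpressionSet(m, c(s1 = "case", s2 = "control")),
                 "without labels")
})
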