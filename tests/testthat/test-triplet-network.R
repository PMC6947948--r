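test_that("single-assignment triangles enumerate exactly once", {
    g <- graphFromSpec("A-B B-C A-C")
    catalog <- GeneRoleCatalog(c("A", "B", "C"),
                               c("IMMUNE", "INFLAMMATION", "DISEASE"))
    ts <- enumerateTriplets(g, catalog)
    expect_equal(triplets(ts),
                 data.frame(immune = "A", inflammation = "B",
                            disease = "C", stringsAsFactors = FALSE))
})

test_that("multifunction genes take the role that completes a triplet", {
    ## D can be immune or inflammation, but E is immune-only, so D must
    ## take inflammation: exactly one assignment.
    g <- graphFromSpec("D-E E-C D-C")
    catalog <- GeneRoleCatalog(c("D", "D", "E", "C"),
                               c("IMMUNE", "INFLAMMATION", "IMMUNE",
                                 "DISEASE"))
    ts <- enumerateTriplets(g, catalog)
    expect_equal(nrow(triplets(ts)), 1L)
    expect_equal(triplets(ts)$inflammation, "D")

    ## no inflammation-capable gene: no triplet
    cat2 <- GeneRoleCatalog(c("D", "E", "C"),
                            c("IMMUNE", "IMMUNE", "DISEASE"))
    expect_equal(length(enumerateTriplets(g, cat2)), 0L)

    ## empty graph
    expect_equal(length(enumerateTriplets(igraph::make_empty_graph(
        0, directed = FALSE), catalog)), 0L)
})

test_that("enumeration matches brute force on random graphs", {
    set.seed(421)
    for (rep in 1:25) {
        n <- sample(4:20, 1)
        g <- randomGraph(n, runif(1, 0.1, 0.5))
        catalog <- randomCatalog(igraph::V(g)$name)
        fast <- triplets(enumerateTriplets(g, catalog))
        slow <- bruteForceTriplets(g, catalog)
        expect_equal(fast, slow)
    }
})

test_that("enumeration is invariant to edge input order", {
    set.seed(7)
    g <- randomGraph(12, 0.4)
    catalog <- randomCatalog(igraph::V(g)$name)
    el <- igraph::as_edgelist(g)
    perm <- sample(nrow(el))
    g2 <- graphFromSpec(paste(el[perm, 1], el[perm, 2], sep = "-",
                              collapse = " "))
    expect_equal(triplets(enumerateTriplets(g, catalog)),
                 triplets(enumerateTriplets(g2, catalog)))
})

test_that("first-assignment mode yields one triplet per triangle", {
    g <- graphFromSpec("A-B B-C A-C")
    catalog <- GeneRoleCatalog(rep(c("A", "B", "C"), each = 3),
                               rep(c("IMMUNE", "INFLAMMATION", "DISEASE"),
                                   3))
    expect_equal(length(enumerateTriplets(g, catalog, mode = "all")), 6L)
    expect_equal(length(enumerateTriplets(g, catalog, mode = "first")), 1L)
})

test_that("triplet network holds exactly the union of triangle edges", {
    catalog <- GeneRoleCatalog(c("A", "B", "C", "D"),
                               list("IMMUNE", "INFLAMMATION", "DISEASE",
                                    "DISEASE"))
    one <- TripletSet("A", "B", "C")
    net1 <- buildTripletNetwork(one, catalog)
    expect_equal(igraph::vcount(net1), 3L)
    expect_equal(igraph::ecount(net1), 3L)

    ## two triplets sharing edge A-B: 4 nodes, 5 edges
    two <- TripletSet(c("A", "A"), c("B", "B"), c("C", "D"))
    net2 <- buildTripletNetwork(two, catalog)
    expect_equal(igraph::vcount(net2), 4L)
    expect_equal(igraph::ecount(net2), 5L)
    expect_setequal(igraph::V(net2)$roleCategory,
                    c("immune", "inflammation", "disease", "disease"))

    empty <- buildTripletNetwork(TripletSet(), catalog)
    expect_equal(igraph::vcount(empty), 0L)

    ## every triplet edge present, no extras (property on random sets)
    set.seed(99)
    g <- randomGraph(20, 0.35)
    rc <- randomCatalog(igraph::V(g)$name)
    ts <- enumerateTriplets(g, rc)
    if (length(ts) > 0) {
        net <- buildTripletNetwork(ts, rc)
        el <- igraph::as_edgelist(net)
        netKeys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
        tdf <- triplets(ts)
        triKeys <- unique(c(
            paste(pmin(tdf$immune, tdf$inflammation),
                  pmax(tdf$immune, tdf$inflammation)),
            paste(pmin(tdf$immune, tdf$disease),
                  pmax(tdf$immune, tdf$disease)),
            paste(pmin(tdf$inflammation, tdf$disease),
                  pmax(tdf$inflammation, tdf$disease))))
        expect_setequal(netKeys, triKeys)
        ## degree sum identity
        expect_equal(sum(igraph::degree(net)), 2 * igraph::ecount(net))
    }
})

test_that("scale-free fit reproduces closed-form OLS", {
    ## star K1,5 + two extra edges gives >=3 distinct degrees
    g <- graphFromSpec("H-A H-B H-C H-D H-E A-B A-C")
    res <- scaleFreeFit(g)
    deg <- igraph::degree(g)
    tab <- table(deg)
    ols <- stats::lm(log10(as.numeric(tab)) ~
                         log10(as.numeric(names(tab))))
    expect_equal(res$slope, unname(coef(ols)[2]))
    expect_equal(res$rSquared, summary(ols)$r.squared)
    expect_equal(sum(res$degree), 2 * igraph::ecount(g))

    ## all-equal degrees: fit undefined
    tri <- graphFromSpec("A-B B-C A-C")
    expect_error(scaleFreeFit(tri), "distinct")
})
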