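## Shared fixture builders; everything is generated in code.

## Small labelled expression container from a plain matrix.
makeSE <- function(m, nCase, nCtrl) {
    colnames(m) <- c(sprintf("CASE%02d", seq_len(nCase)),
                     sprintf("CTRL%02d", seq_len(nCtrl)))
    labels <- stats::setNames(
        c(rep("case", nCase), rep("control", nCtrl)), colnames(m))
    makeExpressionSet(m, labels)
}

## igraph from an edge string like "A-B B-C A-C".
graphFromSpec <- function(edgeSpec, isolated = character()) {
    pairs <- strsplit(strsplit(edgeSpec, " ", fixed = TRUE)[[1]], "-",
                      fixed = TRUE)
    a <- vapply(pairs, `[`, character(1), 1)
    b <- vapply(pairs, `[`, character(1), 2)
    verts <- sort(unique(c(a, b, isolated)))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(verts), name = verts)
    igraph::add_edges(g, rbind(a, b))
}

## Random simple undirected graph on n named nodes.
randomGraph <- function(n, p) {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    g
}

## Random role catalog: every gene gets 1-2 roles.
randomCatalog <- function(geneNames, multiProb = 0.3) {
    roles <- lapply(geneNames, function(g) {
        k <- 1L + (stats::runif(1) < multiProb)
        sample(c("IMMUNE", "INFLAMMATION", "DISEASE"), k)
    })
    GeneRoleCatalog(geneNames, roles)
}

## Brute-force triplet enumeration: all C(n,3) gene triples x 6 role
## assignments, requiring all three pairwise edges. Independent of the
## package's triangle-based path.
bruteForceTriplets <- function(graph, catalog) {
    vn <- sort(igraph::V(graph)$name)
    rl <- geneRoles(catalog)
    hasRole <- function(role) vapply(vn, function(g)
        !is.null(rl[[g]]) && role %in% rl[[g]], logical(1))
    isIm <- hasRole("IMMUNE"); isIn <- hasRole("INFLAMMATION")
    isDi <- hasRole("DISEASE")
    A <- matrix(FALSE, length(vn), length(vn),
                dimnames = list(vn, vn))
    el <- igraph::as_edgelist(graph)
    A[el] <- TRUE; A[el[, c(2, 1), drop = FALSE]] <- TRUE
    out <- list()
    if (length(vn) >= 3) {
        combos <- utils::combn(seq_along(vn), 3)
        for (ci in seq_len(ncol(combos))) {
            i3 <- combos[, ci]
            if (!(A[i3[1], i3[2]] && A[i3[1], i3[3]] &&
                  A[i3[2], i3[3]])) next
            for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
                p3 <- i3[perm]
                if (isIm[p3[1]] && isIn[p3[2]] && isDi[p3[3]])
                    out[[length(out) + 1L]] <- vn[p3]
            }
        }
    }
    if (length(out) == 0L)
        return(data.frame(immune = character(),
                          inflammation = character(),
                          disease = character()))
    df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
    names(df) <- c("immune", "inflammation", "disease")
    df <- df[order(df$immune, df$inflammation, df$disease), ]
    rownames(df) <- NULL
    df
}

## Exhaustive best-cohesiveness subset over ALL non-empty subsets; oracle
## for the objective the greedy search maximises.
bestSubsetCohesiveness <- function(graph, penalty = 2) {
    vn <- igraph::V(graph)$name
    best <- -Inf
    for (k in seq_along(vn)) {
        combos <- utils::combn(vn, k)
        for (ci in seq_len(ncol(combos))) {
            coh <- cohesiveness(graph, combos[, ci], penalty)
            if (coh > best) best <- coh
        }
    }
    best
}

## Tiny scenario used by several tests (fast to score).
tinyScenario <- function(seed = 5L, nPlanted = 3, nNull = 10) {
    simulateScenario(simulationConfig(
        nGenes = 3 * (nPlanted + nNull) + 20,
        nTrianglesPlanted = nPlanted, nTrianglesNull = nNull,
        backgroundEdgeProb = 0.01, nCase = 10, nCtrl = 10, seed = seed))
}
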