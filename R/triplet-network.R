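#' @include catalog.R
NULL

## The six ways to assign the three roles to an ordered gene triple,
## expressed as index permutations of (immune, inflammation, disease).
.ROLE_PERMS <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Construct a triplet set
#'
#' @param immune,inflammation,disease character vectors of gene symbols,
#'   recycled to a common length; each row must consist of three distinct
#'   genes.
#' @return A \linkS4class{TripletSet}.
#' @export
TripletSet <- function(immune = character(), inflammation = character(),
                       disease = character()) {
    el <- data.frame(immune = normalizeSymbol(immune),
                     inflammation = normalizeSymbol(inflammation),
                     disease = normalizeSymbol(disease),
                     stringsAsFactors = FALSE)
    new("TripletSet", elements = el)
}

#' @describeIn TripletSet the triplet table (one row per triplet).
#' @param x a \code{TripletSet}.
#' @param ... unused.
#' @export
setMethod("triplets", "TripletSet", function(x, ...) x@elements)

setMethod("length", "TripletSet", function(x) nrow(x@elements))

setMethod("show", "TripletSet", function(object) {
    cat(sprintf("TripletSet with %d triplet(s) over %d gene(s)\n",
                length(object),
                length(unique(unlist(object@elements)))))
    if (length(object) > 0L)
        print(utils::head(object@elements, 5L))
})

setMethod("as.data.frame", "TripletSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@elements)

#' Enumerate role-assigned triplets from a PPI graph
#'
#' Finds every triangle in the interaction graph and every valid assignment
#' of the immune, inflammation and disease roles to its three (distinct)
#' genes, as licensed by the role catalog. A triangle of multifunctional
#' genes can therefore yield up to six triplets; with
#' \code{mode = "first"} only the first valid assignment (in a fixed
#' permutation order) is kept per triangle. Since the three genes of a
#' triangle are distinct, no gene ever fills two role slots of the same
#' triplet. Output is sorted lexicographically by (immune, inflammation,
#' disease).
#'
#' @param graph undirected simple \code{igraph} with vertex names.
#' @param catalog a \linkS4class{GeneRoleCatalog}.
#' @param mode \code{"all"} (every valid assignment, default) or
#'   \code{"first"} (one assignment per triangle).
#' @return A \linkS4class{TripletSet}.
#' @export
enumerateTriplets <- function(graph, catalog, mode = c("all", "first")) {
    mode <- match.arg(mode)
    if (igraph::vcount(graph) == 0L || igraph::ecount(graph) == 0L)
        return(TripletSet())
    tri <- igraph::triangles(graph)
    if (length(tri) == 0L) return(TripletSet())
    tm <- matrix(igraph::V(graph)$name[as.integer(tri)],
                 ncol = 3L, byrow = TRUE)
    roleSets <- geneRoles(catalog)
    hasRole <- function(sym, role) {
        r <- roleSets[[sym]]
        !is.null(r) && role %in% r
    }
    im <- character(); inf <- character(); dis <- character()
    for (i in seq_len(nrow(tm))) {
        g3 <- tm[i, ]
        for (p in seq_len(nrow(.ROLE_PERMS))) {
            idx <- .ROLE_PERMS[p, ]
            if (hasRole(g3[idx[1]], "IMMUNE") &&
                hasRole(g3[idx[2]], "INFLAMMATION") &&
                hasRole(g3[idx[3]], "DISEASE")) {
                im <- c(im, g3[idx[1]])
                inf <- c(inf, g3[idx[2]])
                dis <- c(dis, g3[idx[3]])
                if (mode == "first") break
            }
        }
    }
    ts <- TripletSet(im, inf, dis)
    el <- ts@elements
    el <- el[order(el$immune, el$inflammation, el$disease), , drop = FALSE]
    el <- el[!duplicated(el), , drop = FALSE]
    rownames(el) <- NULL
    new("TripletSet", elements = el)
}

## The three undirected edges of each triplet, as a 2-column symbol matrix.
tripletEdges <- function(tripletSet) {
    el <- triplets(tripletSet)
    if (nrow(el) == 0L)
        return(matrix(character(), ncol = 2L))
    rbind(cbind(el$immune, el$inflammation),
          cbind(el$immune, el$disease),
          cbind(el$inflammation, el$disease))
}

## Simple undirected igraph from a 2-col symbol matrix + role annotation.
graphFromEdges <- function(edgeMat, catalog = NULL) {
    if (nrow(edgeMat) == 0L)
        return(igraph::make_empty_graph(0, directed = FALSE))
    a <- pmin(edgeMat[, 1], edgeMat[, 2])
    b <- pmax(edgeMat[, 1], edgeMat[, 2])
    keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
    verts <- sort(unique(c(a, b)))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(verts), name = verts)
    g <- igraph::add_edges(g, rbind(a[keep], b[keep]))
    if (!is.null(catalog)) {
        cats <- roleCategories(catalog)
        igraph::V(g)$roleCategory <-
            unname(ifelse(verts %in% names(cats), cats[verts], "none"))
    }
    g
}

#' Build the global triplet network
#'
#' Nodes are the genes of the supplied triplets, edges the (deduplicated)
#' union of each triplet's three triangle edges. Node role-category labels
#' come from the catalog (a gene's full role set), not from any single
#' triplet's assignment.
#'
#' @param tripletSet a \linkS4class{TripletSet}.
#' @param catalog the \linkS4class{GeneRoleCatalog} used for enumeration.
#' @return An \code{igraph} with vertex attribute \code{roleCategory}.
#' @export
buildTripletNetwork <- function(tripletSet, catalog) {
    graphFromEdges(tripletEdges(tripletSet), catalog)
}

#' Scale-free fit of a degree distribution
#'
#' Tabulates the degree frequencies n(k) for observed degrees k >= 1 and
#' fits ordinary least squares to (log10 k, log10 n(k)), the usual
#' log-log degree-distribution check for approximate power-law behaviour.
#'
#' @param graph an \code{igraph}.
#' @return list with \code{slope}, \code{rSquared} and the named
#'   \code{degree} vector.
#' @export
scaleFreeFit <- function(graph) {
    deg <- igraph::degree(graph)
    names(deg) <- igraph::V(graph)$name
    tab <- table(deg[deg >= 1])
    k <- as.numeric(names(tab))
    nk <- as.numeric(tab)
    if (length(k) < 3L)
        stop("scale-free fit needs >=3 distinct observed degree values")
    fit <- stats::lm(log10(nk) ~ log10(k))
    list(slope = unname(stats::coef(fit)[2]),
         rSquared = summary(fit)$r.squared,
         degree = deg)
}

#' Write a triplet table as TSV
#'
#' Columns \code{immune_gene}, \code{inflammation_gene},
#' \code{disease_gene}; when given a score table (from
#' \code{\link{scoreTriplets}} and friends) all score columns are appended.
#'
#' @param x a \code{TripletSet} or a score \code{DataFrame}.
#' @param path output path.
#' @export
writeTripletTable <- function(x, path) {
    df <- if (is(x, "TripletSet")) triplets(x) else as.data.frame(x)
    names(df)[names(df) == "immune"] <- "immune_gene"
    names(df)[names(df) == "inflammation"] <- "inflammation_gene"
    names(df)[names(df) == "disease"] <- "disease_gene"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
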