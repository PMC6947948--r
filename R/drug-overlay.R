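#' @include scoring.R
NULL

#' Overlay drug-target interactions on the dysregulated network
#'
#' Keeps the dysregulated gene network unchanged and adds one drug node
#' per drug with at least one target among its genes, connected to each
#' such target. Vertices carry \code{nodeType} (\code{"gene"} or
#' \code{"drug"}); drug vertices are named by drug id and carry the
#' display name in \code{drugName}; gene vertices keep their
#' \code{roleCategory}.
#'
#' @param dys a \linkS4class{DysregulatedNetwork} or an \code{igraph} of
#'   genes.
#' @param drugs drug-target data.frame from \code{\link{readDrugTargets}}
#'   (columns \code{drugId}, \code{drugName}, \code{gene}).
#' @return An \code{igraph} with gene-gene and drug-gene edges.
#' @export
buildDrugNetwork <- function(dys, drugs) {
    g <- if (is(dys, "DysregulatedNetwork")) networkGraph(dys) else dys
    geneNames <- igraph::V(g)$name
    igraph::V(g)$nodeType <- "gene"
    igraph::V(g)$drugName <- NA_character_
    if (nrow(drugs) == 0L) return(g)
    drugs <- drugs[!duplicated(drugs[, c("drugId", "gene")]), , drop = FALSE]
    hit <- drugs[drugs$gene %in% geneNames, , drop = FALSE]
    if (nrow(hit) == 0L) return(g)
    ids <- sort(unique(hit$drugId))
    nameOf <- tapply(hit$drugName, hit$drugId, `[`, 1L)
    g <- igraph::add_vertices(g, length(ids), name = ids,
                              nodeType = "drug",
                              drugName = as.character(nameOf[ids]),
                              roleCategory = NA_character_)
    hit <- hit[order(hit$drugId, hit$gene), , drop = FALSE]
    g <- igraph::add_edges(g, rbind(hit$drugId, hit$gene))
    g
}

#' Rank drugs by degree in the drug-overlay network
#'
#' @param net drug network from \code{\link{buildDrugNetwork}}.
#' @return A \code{DataFrame} with \code{drugId}, \code{drugName},
#'   \code{degree} and \code{targets} (\code{CharacterList}), in
#'   descending degree (ties broken lexicographically by drug id).
#' @export
rankDrugsByDegree <- function(net) {
    isDrug <- igraph::V(net)$nodeType == "drug"
    ids <- igraph::V(net)$name[isDrug]
    if (length(ids) == 0L)
        return(DataFrame(drugId = character(), drugName = character(),
                         degree = integer(),
                         targets = IRanges::CharacterList()))
    targets <- lapply(ids, function(d)
        sort(igraph::neighbors(net, d)$name))
    deg <- lengths(targets)
    ord <- order(-deg, ids)
    DataFrame(drugId = ids[ord],
              drugName = igraph::V(net)$drugName[isDrug][ord],
              degree = as.integer(deg[ord]),
              targets = IRanges::CharacterList(targets[ord]))
}

#' Extract the subnetwork around one drug
#'
#' The drug node, its target genes present in the network, and the
#' gene-gene edges among those targets.
#'
#' @param net drug network from \code{\link{buildDrugNetwork}}.
#' @param drugId drug identifier (must be present).
#' @return An \code{igraph}.
#' @export
extractDrugSubnetwork <- function(net, drugId) {
    isDrug <- igraph::V(net)$nodeType == "drug"
    if (!drugId %in% igraph::V(net)$name[isDrug])
        stop("drug not present in network: ", drugId)
    keep <- c(drugId, igraph::neighbors(net, drugId)$name)
    igraph::induced_subgraph(net, keep)
}

#' Write the drug ranking as TSV
#'
#' @param ranking \code{DataFrame} from \code{\link{rankDrugsByDegree}}.
#' @param path output path.
#' @export
writeDrugRanking <- function(ranking, path) {
    df <- data.frame(drug_id = ranking$drugId,
                     drug_name = ranking$drugName,
                     degree = ranking$degree,
                     targets = vapply(ranking$targets, paste,
                                      character(1), collapse = ";"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
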