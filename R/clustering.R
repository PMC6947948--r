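#' @include scoring.R
NULL

#' Cohesiveness of a node subset
#'
#' The cluster quality used for core-cluster extraction:
#' \deqn{w_{in} / (w_{in} + w_{bound} + p\,|V|)}
#' with unit edge weights, where \eqn{w_{in}} counts edges inside the
#' subset, \eqn{w_{bound}} edges with exactly one endpoint inside, and
#' \eqn{p} a per-node penalty modelling unobserved interactions.
#'
#' @param graph an \code{igraph} with vertex names.
#' @param members character vector of node names (non-empty, subset of the
#'   graph's nodes).
#' @param penalty per-node penalty (default 2, the customary default of
#'   cohesiveness-based complex detection).
#' @return cohesiveness in [0, 1].
#' @export
cohesiveness <- function(graph, members, penalty = 2) {
    if (length(members) == 0L) stop("empty subset")
    vn <- igraph::V(graph)$name
    if (!all(members %in% vn)) stop("subset contains unknown nodes")
    el <- igraph::as_edgelist(graph)
    inA <- el[, 1] %in% members
    inB <- el[, 2] %in% members
    wIn <- sum(inA & inB)
    wBound <- sum(xor(inA, inB))
    wIn / (wIn + wBound + penalty * length(members))
}

## Incremental cohesiveness machinery: track wIn/wBound while moving single
## vertices, using adjacency lists.
.adjList <- function(graph) {
    vn <- igraph::V(graph)$name
    lapply(stats::setNames(seq_along(vn), vn),
           function(i) vn[igraph::neighbors(graph, i)])
}

#' Greedy cohesiveness-based core clusters
#'
#' ClusterONE-style detection of dense, well-separated node groups: grow a
#' candidate from each seed (uncovered nodes in decreasing-degree order) by
#' single-vertex additions/removals that maximise cohesiveness, merge
#' candidate pairs whose overlap score \eqn{|A\cap B|^2/(|A||B|)} reaches
#' \code{overlapMerge}, filter by minimum size and induced edge density,
#' and return the \code{topN} clusters by cohesiveness (ties broken by the
#' lexicographic member list).
#'
#' @param graph non-empty \code{igraph} with vertex names.
#' @param penalty per-node cohesiveness penalty.
#' @param overlapMerge overlap-score threshold for merging candidates.
#' @param minSize minimum cluster size.
#' @param minDensity minimum induced edge density.
#' @param topN number of clusters to return.
#' @return A \code{DataFrame} with columns \code{members}
#'   (\code{CharacterList}), \code{size}, \code{density} and
#'   \code{cohesiveness}, ordered by decreasing cohesiveness.
#' @export
greedyCohesiveClusters <- function(graph, penalty = 2, overlapMerge = 0.8,
                                   minSize = 3, minDensity = 0.5,
                                   topN = 4) {
    if (igraph::vcount(graph) == 0L) stop("empty graph")
    vn <- igraph::V(graph)$name
    adj <- .adjList(graph)
    deg <- vapply(adj, length, integer(1))
    seeds <- vn[order(-deg, vn)]
    covered <- character()
    candidates <- list()
    for (seed in seeds) {
        if (seed %in% covered) next
        cl <- growCluster(adj, seed, penalty)
        candidates[[length(candidates) + 1L]] <- cl
        covered <- union(covered, cl)
    }
    ## connected components are natural zero-boundary candidates that the
    ## vertex-by-vertex climb can miss when a fitness valley separates
    ## them from every seed's trajectory
    comp <- igraph::components(graph)
    for (ci in seq_len(comp$no)) {
        members <- vn[comp$membership == ci]
        if (length(members) > 1L)
            candidates[[length(candidates) + 1L]] <- sort(members)
    }
    candidates <- mergeOverlapping(candidates, overlapMerge)
    keep <- list(); coh <- numeric(); dens <- numeric()
    for (cl in candidates) {
        s <- length(cl)
        if (s < minSize) next
        wIn <- sum(vapply(cl, function(v) sum(adj[[v]] %in% cl),
                          numeric(1))) / 2
        d <- if (s > 1) wIn / (s * (s - 1) / 2) else 0
        if (d < minDensity) next
        keep[[length(keep) + 1L]] <- sort(cl)
        dens <- c(dens, d)
        coh <- c(coh, cohesiveness(graph, cl, penalty))
    }
    if (length(keep) == 0L)
        return(DataFrame(members = IRanges::CharacterList(),
                         size = integer(), density = numeric(),
                         cohesiveness = numeric()))
    tieKey <- vapply(keep, paste, character(1), collapse = ",")
    ord <- order(-coh, tieKey)
    ord <- ord[seq_len(min(topN, length(ord)))]
    DataFrame(members = IRanges::CharacterList(keep[ord]),
              size = lengths(keep)[ord],
              density = dens[ord],
              cohesiveness = coh[ord])
}

## Grow/shrink one candidate by single-vertex hill climbing. Sideways
## (equal-cohesiveness) moves to unvisited states are allowed so that
## plateaus separating a seed from a better region can be crossed; the
## best state seen along the trajectory is returned. Deterministic
## tie-breaking: additions before removals, then vertex name.
growCluster <- function(adj, seed, penalty) {
    coh <- function(wi, wb, s) wi / (wi + wb + penalty * s)
    cl <- seed
    wIn <- 0
    wBound <- length(adj[[seed]])
    cur <- coh(wIn, wBound, 1L)
    bestSet <- cl; bestCoh <- cur
    visited <- new.env(parent = emptyenv())
    assign(paste(sort(cl), collapse = "\r"), TRUE, envir = visited)
    maxIter <- 50L + 10L * length(adj)
    for (iter in seq_len(maxIter)) {
        moves <- list()
        boundary <- sort(setdiff(unique(unlist(adj[cl])), cl))
        for (v in boundary) {
            dIn <- sum(adj[[v]] %in% cl)         # edges v -> cluster
            dOut <- length(adj[[v]]) - dIn
            wi <- wIn + dIn; wb <- wBound - dIn + dOut
            moves[[length(moves) + 1L]] <-
                list(set = c(cl, v), wi = wi, wb = wb,
                     coh = coh(wi, wb, length(cl) + 1L))
        }
        if (length(cl) > 1L) for (v in sort(cl)) {
            dIn <- sum(adj[[v]] %in% cl)
            dOut <- length(adj[[v]]) - dIn
            wi <- wIn - dIn; wb <- wBound + dIn - dOut
            moves[[length(moves) + 1L]] <-
                list(set = setdiff(cl, v), wi = wi, wb = wb,
                     coh = coh(wi, wb, length(cl) - 1L))
        }
        if (length(moves) == 0L) break
        ## never move downhill; prefer the highest cohesiveness among
        ## states not yet visited
        keys <- vapply(moves, function(m)
            paste(sort(m$set), collapse = "\r"), character(1))
        fresh <- !vapply(keys, exists, logical(1), envir = visited)
        ok <- fresh & vapply(moves, function(m)
            m$coh >= cur - 1e-12, logical(1))
        if (!any(ok)) break
        cand <- which(ok)
        pick <- cand[order(-vapply(moves[cand], `[[`, numeric(1), "coh"),
                           keys[cand])][1]
        m <- moves[[pick]]
        cl <- m$set; wIn <- m$wi; wBound <- m$wb; cur <- m$coh
        assign(keys[pick], TRUE, envir = visited)
        if (cur > bestCoh + 1e-12) { bestCoh <- cur; bestSet <- cl }
    }
    sort(bestSet)
}

## Merge candidate clusters whose overlap score reaches the threshold.
mergeOverlapping <- function(cands, threshold) {
    cands <- unique(lapply(cands, sort))
    repeat {
        merged <- FALSE
        n <- length(cands)
        if (n < 2L) break
        for (i in seq_len(n - 1L)) {
            for (j in (i + 1L):n) {
                A <- cands[[i]]; B <- cands[[j]]
                ov <- length(intersect(A, B))^2 / (length(A) * length(B))
                if (ov >= threshold) {
                    cands[[i]] <- sort(union(A, B))
                    cands[[j]] <- NULL
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }
    cands
}

#' Chi-square association between cluster assignment and disease status
#'
#' Pearson chi-square (no continuity correction) on the group-by-status
#' contingency table. Groups with zero samples are dropped with a warning;
#' a table left with fewer than two rows or columns is degenerate and
#' raises an error.
#'
#' @param assignment named vector, sample -> group.
#' @param labels named vector or factor, sample -> case/control (also
#'   accepts a \code{SummarizedExperiment} with \code{condition} labels).
#' @return list with \code{contingency}, \code{chi2}, \code{df}, \code{p}.
#' @export
clusterDiseaseAssociation <- function(assignment, labels) {
    if (is(labels, "SummarizedExperiment"))
        labels <- stats::setNames(
            as.character(SummarizedExperiment::colData(labels)$condition),
            colnames(labels))
    samples <- names(assignment)
    if (is.null(samples) || !all(samples %in% names(labels)))
        stop("every assigned sample needs a disease label")
    tab <- table(group = factor(assignment[samples]),
                 status = normalizeLabels(labels[samples]))
    empty <- rowSums(tab) == 0
    if (any(empty)) {
        warning("dropping ", sum(empty), " empty group(s) from the table")
        tab <- tab[!empty, , drop = FALSE]
    }
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
        stop("degenerate contingency table: need >=2 groups and >=2 statuses")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(contingency = tab, chi2 = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value)
}
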