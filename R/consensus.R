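#' @include clustering.R
NULL

#' Subsampled k-means consensus clustering of samples
#'
#' For each candidate group count k in 2..\code{kMax}, repeatedly
#' subsamples the samples, runs k-means (Euclidean, 10 restarts per
#' resample, a fixed RNG stream per (k, resample)) on the sample profiles,
#' and accumulates the consensus matrix \eqn{M(i,j)} = co-clustered count /
#' co-sampled count. Model selection follows the area under the empirical
#' CDF of consensus values: \code{deltaArea(2) = cdfArea(2)} and, for
#' k > 2, the relative increase
#' \code{(cdfArea(k) - cdfArea(k-1)) / cdfArea(k-1)}; the chosen k is the
#' largest k whose delta-area still reaches the elbow threshold (i.e. the
#' last k before the increase in CDF area becomes small). The final
#' assignment cuts an average-linkage hierarchical clustering of
#' \code{1 - M} at the chosen k.
#'
#' @param x expression for one core cluster: a gene-by-sample matrix or a
#'   \code{SummarizedExperiment} (optionally restricted with
#'   \code{genes}).
#' @param kMax largest group count to evaluate (>= 2; needs at least
#'   \code{kMax + 1} samples).
#' @param nResamples number of subsamples per k (default 100).
#' @param subsampleFrac fraction of samples drawn per resample
#'   (default 0.8).
#' @param seed integer seed; consensus matrices are bit-reproducible under
#'   a fixed seed.
#' @param elbow delta-area threshold for choosing k (default 0.1).
#' @param genes optional gene subset when \code{x} is a
#'   \code{SummarizedExperiment}.
#' @return A \linkS4class{ConsensusReport}.
#' @export
consensusCluster <- function(x, kMax, nResamples = 100,
                             subsampleFrac = 0.8, seed = 1L, elbow = 0.1,
                             genes = NULL) {
    if (kMax < 2L) stop("kMax must be >= 2")
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "expr")
        if (!is.null(genes)) {
            genes <- intersect(normalizeSymbol(genes), rownames(m))
            if (length(genes) == 0L) stop("no requested genes present")
            m <- m[genes, , drop = FALSE]
        }
    } else m <- x
    if (nrow(m) < 1L) stop("need >=1 gene")
    profiles <- t(m)                       # samples as observations
    n <- nrow(profiles)
    if (n < kMax + 1L) stop("need >= kMax + 1 samples")
    sampleNames <- rownames(profiles)
    if (is.null(sampleNames)) sampleNames <- paste0("S", seq_len(n))
    unstable <- max(stats::dist(profiles)) < 1e-12
    kValues <- 2L:as.integer(kMax)
    consensus <- list()
    for (k in kValues) {
        hits <- matrix(0, n, n)
        together <- matrix(0, n, n)
        for (r in seq_len(nResamples)) {
            set.seed(deriveSeed(seed, 1000L * k + r))
            idx <- sort(sample(n, max(k + 1L, floor(subsampleFrac * n))))
            together[idx, idx] <- together[idx, idx] + 1
            cl <- if (unstable) rep(1L, length(idx)) else
                tryCatch(stats::kmeans(profiles[idx, , drop = FALSE],
                                       centers = k, nstart = 10,
                                       iter.max = 50)$cluster,
                         error = function(e) rep(1L, length(idx)))
            same <- outer(cl, cl, "==")
            hits[idx, idx] <- hits[idx, idx] + same
        }
        M <- ifelse(together > 0, hits / together, 0)
        diag(M) <- 1
        M <- (M + t(M)) / 2
        dimnames(M) <- list(sampleNames, sampleNames)
        consensus[[as.character(k)]] <- M
    }
    areas <- vapply(consensus, function(M)
        consensusCDFArea(M[upper.tri(M)]), numeric(1))
    ## numerical guard: tiny non-monotonicities from ties are clamped
    areas <- cummax(areas)
    delta <- numeric(length(kValues))
    delta[1] <- areas[1]
    if (length(kValues) > 1L)
        delta[-1] <- diff(areas) / utils::head(areas, -1L)
    passing <- kValues[delta >= elbow]
    chosen <- if (length(passing)) max(passing) else kValues[1]
    Mc <- consensus[[as.character(chosen)]]
    assignment <- if (unstable) {
        stats::setNames(rep(1L, n), sampleNames)
    } else {
        hc <- stats::hclust(stats::as.dist(1 - Mc), method = "average")
        stats::setNames(as.integer(stats::cutree(hc, k = chosen)),
                        sampleNames)
    }
    new("ConsensusReport", kValues = kValues, consensus = consensus,
        cdfArea = stats::setNames(as.numeric(areas), names(consensus)),
        deltaArea = stats::setNames(delta, names(consensus)),
        chosenK = as.integer(chosen), assignment = assignment,
        unstable = unstable)
}

## Trapezoidal area under the empirical CDF of consensus values over [0,1].
consensusCDFArea <- function(vals) {
    grid <- sort(unique(c(0, vals, 1)))
    cdf <- stats::ecdf(vals)(grid)
    trapezoidArea(grid, cdf)
}

#' @describeIn consensusCluster selected number of sample groups.
#' @param ... unused.
#' @export
setMethod("chosenK", "ConsensusReport", function(x, ...) x@chosenK)

#' @describeIn consensusCluster consensus matrix for one k (default: the
#'   chosen k).
#' @param k group count whose consensus matrix to return.
#' @export
setMethod("consensusMatrix", "ConsensusReport", function(x, k, ...) {
    if (missing(k)) k <- x@chosenK
    M <- x@consensus[[as.character(k)]]
    if (is.null(M)) stop("k = ", k, " was not evaluated")
    M
})

#' @describeIn consensusCluster CDF areas per tested k.
#' @export
setMethod("cdfArea", "ConsensusReport", function(x, ...) x@cdfArea)

#' @describeIn consensusCluster relative delta areas per tested k.
#' @export
setMethod("deltaArea", "ConsensusReport", function(x, ...) x@deltaArea)

#' @describeIn consensusCluster final sample -> group assignment.
#' @export
setMethod("sampleAssignment", "ConsensusReport", function(x, ...)
    x@assignment)

setMethod("show", "ConsensusReport", function(object) {
    cat(sprintf("ConsensusReport: k in {%s}, chosen k = %d%s\n",
                paste(object@kValues, collapse = ", "), object@chosenK,
                if (object@unstable) " (unstable: degenerate input)" else ""))
    cat("  cdfArea:  ", paste(sprintf("%.3f", object@cdfArea),
                              collapse = " "), "\n")
    cat("  deltaArea:", paste(sprintf("%.3f", object@deltaArea),
                              collapse = " "), "\n")
})

#' Write a consensus report to disk
#'
#' JSON summary (k values, CDF/delta areas, chosen k, assignment) plus one
#' consensus-matrix TSV per tested k.
#'
#' @param report a \linkS4class{ConsensusReport}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
writeConsensusReport <- function(report, dir, prefix = "consensus") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    for (k in report@kValues) {
        p <- file.path(dir, sprintf("%s_matrix_k%d.tsv", prefix, k))
        write.table(consensusMatrix(report, k), p, sep = "\t",
                    quote = FALSE)
        paths <- c(paths, p)
    }
    summaryPath <- file.path(dir, paste0(prefix, "_report.json"))
    jsonlite::write_json(
        list(kValues = report@kValues,
             cdfArea = as.list(report@cdfArea),
             deltaArea = as.list(report@deltaArea),
             chosenK = report@chosenK,
             unstable = report@unstable,
             assignment = as.list(report@assignment)),
        summaryPath, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, summaryPath))
}
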