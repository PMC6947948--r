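#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.ROLES <- c("IMMUNE", "INFLAMMATION", "DISEASE")

#' Gene role catalog
#'
#' Maps gene symbols to the set of functional roles they can play in a
#' cross-role triplet: \code{IMMUNE}, \code{INFLAMMATION} and/or
#' \code{DISEASE}. Symbols are case-normalised (uppercase, whitespace
#' stripped) so joins against interaction and expression data are
#' deterministic. Build catalogs with \code{\link{GeneRoleCatalog}} or
#' \code{\link{readGeneRoles}} and combine them with \code{c()}.
#'
#' @slot roles named list; one character vector of roles per gene symbol.
#'
#' @seealso \code{\link{readGeneRoles}}, \code{\link{enumerateTriplets}}
#' @export
setClass("GeneRoleCatalog", representation(roles = "list"))

setValidity("GeneRoleCatalog", function(object) {
    r <- object@roles
    if (length(r) == 0L) return(TRUE)
    if (is.null(names(r)) || anyDuplicated(names(r)))
        return("gene symbols must be unique, non-empty names")
    if (any(!vapply(r, function(x) length(x) >= 1L && all(x %in% .ROLES),
                    logical(1))))
        return(sprintf("every gene needs >=1 role drawn from {%s}",
                       paste(.ROLES, collapse = ", ")))
    if (any(vapply(r, anyDuplicated, integer(1)) > 0L))
        return("role sets must not contain duplicates")
    TRUE
})

#' Set of role-assigned triplets
#'
#' A triplet is three pairwise-distinct genes forming a triangle in the
#' protein-protein interaction network, with an explicit assignment of the
#' immune, inflammation and disease roles, one per gene. A single triangle
#' whose genes are multifunctional can yield several triplets (one per valid
#' role assignment).
#'
#' @slot elements data.frame with character columns \code{immune},
#'   \code{inflammation}, \code{disease}, one row per triplet.
#'
#' @seealso \code{\link{enumerateTriplets}}, \code{\link{scoreTriplets}}
#' @export
setClass("TripletSet", representation(elements = "data.frame"))

setValidity("TripletSet", function(object) {
    el <- object@elements
    need <- c("immune", "inflammation", "disease")
    if (!all(need %in% colnames(el)))
        return("elements must have columns immune, inflammation, disease")
    if (nrow(el) > 0L) {
        same <- el$immune == el$inflammation | el$immune == el$disease |
            el$inflammation == el$disease
        if (any(same))
            return("triplet genes must be pairwise distinct")
    }
    TRUE
})

#' Dysregulated triplet subnetwork
#'
#' The triplets whose permutation p-value falls below the significance
#' threshold, together with the gene network induced by their triangles.
#'
#' @slot records \code{DataFrame} of significant triplet score records
#'   (see \code{\link{scoreTriplets}} / \code{\link{permutationPValues}}).
#' @slot graph \code{igraph} object; nodes carry a \code{roleCategory}
#'   vertex attribute taken from the role catalog.
#' @slot alpha numeric(1); the threshold the records satisfy
#'   (\code{permP < alpha}).
#'
#' @seealso \code{\link{selectDysregulated}}
#' @export
setClass("DysregulatedNetwork",
         representation(records = "DataFrame", graph = "ANY",
                        alpha = "numeric"))

setValidity("DysregulatedNetwork", function(object) {
    rec <- object@records
    if (nrow(rec) > 0L && !is.null(rec$permP) &&
        any(rec$permP >= object@alpha))
        return("all records must satisfy permP < alpha")
    TRUE
})

#' Consensus clustering report
#'
#' Evidence collected while choosing the number of sample groups by
#' subsampled k-means consensus clustering: per-k consensus matrices, the
#' area under the CDF of consensus values, the relative delta-area used for
#' model selection, the chosen k and the final sample assignment.
#'
#' @slot kValues integer vector of tested group counts (2..kMax).
#' @slot consensus named list of sample-by-sample consensus matrices, one
#'   per tested k; symmetric with unit diagonal, entries in [0,1].
#' @slot cdfArea numeric; area under the empirical CDF of upper-triangle
#'   consensus values, per k.
#' @slot deltaArea numeric; relative increase in CDF area, per k.
#' @slot chosenK integer(1); selected number of groups.
#' @slot assignment named integer vector, sample -> group.
#' @slot unstable logical(1); TRUE when the input was degenerate (e.g. all
#'   samples identical) and the consensus is not informative.
#'
#' @seealso \code{\link{consensusCluster}}
#' @export
setClass("ConsensusReport",
         representation(kValues = "integer", consensus = "list",
                        cdfArea = "numeric", deltaArea = "numeric",
                        chosenK = "integer", assignment = "integer",
                        unstable = "logical"))

setValidity("ConsensusReport", function(object) {
    for (M in object@consensus) {
        if (!isSymmetric(unname(M), tol = 1e-8))
            return("consensus matrices must be symmetric")
        if (any(abs(diag(M) - 1) > 1e-8))
            return("consensus matrices must have unit diagonal")
        if (any(M < -1e-8 | M > 1 + 1e-8))
            return("consensus entries must lie in [0,1]")
    }
    if (length(object@cdfArea) > 1L &&
        any(diff(object@cdfArea) < -1e-8))
        return("cdfArea must be non-decreasing in k")
    TRUE
})
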