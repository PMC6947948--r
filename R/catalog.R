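#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a gene role catalog
#'
#' @param symbols character vector of gene symbols (normalised to uppercase,
#'   whitespace stripped; duplicates merged by role union).
#' @param roles either a single role applied to all symbols, a character
#'   vector parallel to \code{symbols}, or a list of role vectors parallel
#'   to \code{symbols}. Roles must be among \code{IMMUNE},
#'   \code{INFLAMMATION}, \code{DISEASE}.
#'
#' @return A \linkS4class{GeneRoleCatalog}.
#'
#' @examples
#' cat <- GeneRoleCatalog(c("JAK3", "IL4R"), "IMMUNE")
#' geneRoles(cat)
#' @export
GeneRoleCatalog <- function(symbols = character(), roles = list()) {
    symbols <- normalizeSymbol(symbols)
    keep <- nzchar(symbols)
    symbols <- symbols[keep]
    if (length(symbols) == 0L)
        return(new("GeneRoleCatalog", roles = structure(list(),
                                                        names = character())))
    if (is.character(roles)) {
        roles <- toupper(roles)
        roles <- if (length(roles) == 1L)
            rep(list(roles), length(symbols))
        else as.list(roles[keep])
    } else {
        roles <- lapply(roles[keep], toupper)
    }
    stopifnot(length(roles) == length(symbols))
    merged <- tapply(roles, symbols, function(r)
        sort(unique(unlist(r))), simplify = FALSE)
    out <- lapply(merged, identity)
    new("GeneRoleCatalog", roles = out[sort(names(out))])
}

#' @describeIn GeneRoleCatalog gene symbols in the catalog.
#' @param x a \code{GeneRoleCatalog}.
#' @param ... unused.
#' @export
setMethod("genes", "GeneRoleCatalog", function(x, ...) names(x@roles))

#' @describeIn GeneRoleCatalog named list of role sets per gene.
#' @export
setMethod("geneRoles", "GeneRoleCatalog", function(x, ...) x@roles)

setMethod("length", "GeneRoleCatalog", function(x) length(x@roles))

#' Merge role catalogs by role-set union
#'
#' Merging is commutative and idempotent: a gene appearing in several
#' fragments ends up with the union of its role sets.
#'
#' @param x,... \code{GeneRoleCatalog} objects.
#' @return A merged \code{GeneRoleCatalog}.
#' @export
setMethod("c", "GeneRoleCatalog", function(x, ...) {
    frags <- c(list(x), list(...))
    all <- unlist(lapply(frags, function(f) f@roles), recursive = FALSE)
    GeneRoleCatalog(names(all), all)
})

#' Role-category label per gene
#'
#' Collapses each gene's role set into one of the seven display categories
#' used for network annotation: \code{immune}, \code{inflammation},
#' \code{disease}, \code{immune&inflammation}, \code{disease&immune},
#' \code{disease&inflammation} or \code{all-three}.
#'
#' @param x a \code{GeneRoleCatalog}.
#' @param ... unused.
#' @return named character vector, gene -> category.
#' @export
setMethod("roleCategories", "GeneRoleCatalog", function(x, ...) {
    vapply(x@roles, function(r) {
        r <- sort(r)
        if (length(r) == 3L) return("all-three")
        if (length(r) == 1L) return(tolower(r))
        paste(tolower(r), collapse = "&")
    }, character(1))
})

setMethod("show", "GeneRoleCatalog", function(object) {
    tab <- table(factor(roleCategories(object),
                        levels = c("immune", "inflammation", "disease",
                                   "immune&inflammation", "disease&immune",
                                   "disease&inflammation", "all-three")))
    cat(sprintf("GeneRoleCatalog with %d genes\n", length(object)))
    for (nm in names(tab))
        if (tab[[nm]] > 0L) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
})

## Internal: roles for one symbol ("" set if absent).
rolesOf <- function(catalog, symbol) {
    r <- catalog@roles[[symbol]]
    if (is.null(r)) character() else r
}
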