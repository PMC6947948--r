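#' @include AllClasses.R
NULL

#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @export
setGeneric("geneRoles", function(x, ...) standardGeneric("geneRoles"))

#' @export
setGeneric("roleCategories", function(x, ...)
    standardGeneric("roleCategories"))

#' @export
setGeneric("triplets", function(x, ...) standardGeneric("triplets"))

#' @export
setGeneric("records", function(x, ...) standardGeneric("records"))

#' @export
setGeneric("networkGraph", function(x, ...) standardGeneric("networkGraph"))

#' @export
setGeneric("chosenK", function(x, ...) standardGeneric("chosenK"))

#' @export
setGeneric("consensusMatrix", function(x, k, ...)
    standardGeneric("consensusMatrix"))

#' @export
setGeneric("cdfArea", function(x, ...) standardGeneric("cdfArea"))

#' @export
setGeneric("deltaArea", function(x, ...) standardGeneric("deltaArea"))

#' @export
setGeneric("sampleAssignment", function(x, ...)
    standardGeneric("sampleAssignment"))
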