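#' @include catalog.R
#' @importFrom utils read.table write.table
NULL

#' Read a gene role list (one-symbol-per-line TSV or GMT)
#'
#' Reads a flat list of gene symbols and tags each with \code{role},
#' producing a catalog fragment; fragments for different roles are combined
#' with \code{c()}, which unions role sets per gene. GMT files (tab-separated
#' \code{set-name<TAB>description<TAB>gene...}) contribute all member genes
#' of every set; the role still comes from the \code{role} argument.
#'
#' @param path file path.
#' @param role one of \code{"IMMUNE"}, \code{"INFLAMMATION"},
#'   \code{"DISEASE"}.
#' @param format \code{"auto"} (GMT when the extension is \code{.gmt}),
#'   \code{"tsv"} or \code{"gmt"}.
#' @return A \linkS4class{GeneRoleCatalog} fragment.
#' @export
readGeneRoles <- function(path, role = c("IMMUNE", "INFLAMMATION", "DISEASE"),
                          format = c("auto", "tsv", "gmt")) {
    role <- match.arg(role)
    format <- match.arg(format)
    if (!file.exists(path)) stop("cannot read gene role file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty gene role file: ", path)
    if (format == "auto")
        format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt"
                  else "tsv"
    if (format == "gmt") {
        syms <- unlist(lapply(strsplit(lines, "\t", fixed = TRUE),
                              function(f) {
            if (length(f) < 3L) {
                warning("skipping malformed GMT line: ",
                        substr(f[1], 1, 40))
                return(character())
            }
            f[-(1:2)]
        }))
    } else {
        fields <- strsplit(lines, "\t", fixed = TRUE)
        syms <- vapply(fields, `[`, character(1), 1L)
    }
    syms <- normalizeSymbol(syms)
    syms <- syms[nzchar(syms)]
    if (length(syms) == 0L) stop("no gene symbols found in ", path)
    GeneRoleCatalog(unique(syms), role)
}

#' Read an undirected protein-protein interaction edge list
#'
#' Returns a simple undirected \code{igraph}: self-loops and duplicate
#' (including reversed) pairs are removed and their counts reported via
#' \code{message()}.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} for a generic two-symbol-column layout, or
#'   \code{"hprd"} for the HPRD flat-file layout (symbols in columns 1
#'   and 4).
#' @return An undirected simple \code{igraph} object.
#' @export
readPPIEdges <- function(path, dialect = c("tsv", "hprd")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("cannot read PPI file: ", path)
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
        return(igraph::make_empty_graph(0, directed = FALSE))
    df <- tryCatch(
        read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "",
                   comment.char = "", fill = TRUE),
        error = function(e) stop("unreadable PPI file ", path, ": ",
                                 conditionMessage(e)))
    if (nrow(df) == 0L)
        return(igraph::make_empty_graph(0, directed = FALSE))
    cols <- if (dialect == "hprd") c(1L, 4L) else c(1L, 2L)
    if (ncol(df) < max(cols))
        stop("PPI file has too few columns for dialect '", dialect, "'")
    a <- normalizeSymbol(df[[cols[1]]])
    b <- normalizeSymbol(df[[cols[2]]])
    ok <- nzchar(a) & nzchar(b)
    edgesFromPairs(a[ok], b[ok], dropped = sum(!ok))
}

## Build a simple undirected igraph from symbol pairs, logging drops.
edgesFromPairs <- function(a, b, dropped = 0L) {
    loops <- a == b
    a2 <- pmin(a[!loops], b[!loops])
    b2 <- pmax(a[!loops], b[!loops])
    key <- paste(a2, b2, sep = "\r")
    dup <- duplicated(key)
    nDrop <- dropped + sum(loops) + sum(dup)
    if (nDrop > 0L)
        message(sprintf(
            "dropped %d record(s): %d self-loop(s), %d duplicate pair(s)",
            nDrop, sum(loops), sum(dup)))
    verts <- sort(unique(c(a2, b2)))
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(verts), name = verts)
    if (length(a2))
        g <- igraph::add_edges(g, rbind(a2[!dup], b2[!dup]))
    g
}

#' Write a graph as an edge-list TSV
#'
#' Two symbol columns, one undirected edge per row with endpoints in sorted
#' order; re-reading with \code{\link{readPPIEdges}} round-trips the graph.
#'
#' @param graph an \code{igraph}.
#' @param path output path.
#' @export
writeEdgeList <- function(graph, path) {
    el <- igraph::as_edgelist(graph)
    if (nrow(el)) {
        el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
        el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    }
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an expression matrix with sample labels
#'
#' Reads a TSV matrix (rows = probes or genes, columns = samples, first
#' column = row identifier) plus a two-column labels TSV
#' (\code{sample<TAB>case|control}) into a
#' \code{SummarizedExperiment} whose \code{colData$condition} is a
#' CASE/CONTROL factor.
#'
#' @param path expression TSV path.
#' @param labelsPath labels TSV path.
#' @return A \code{SummarizedExperiment} with assay \code{"expr"}.
#' @export
readExpressionMatrix <- function(path, labelsPath) {
    if (!file.exists(path)) stop("cannot read expression file: ", path)
    df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                     check.names = FALSE, quote = "", comment.char = "")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    labels <- readSampleLabels(labelsPath)
    makeExpressionSet(m, labels)
}

#' @rdname readExpressionMatrix
#' @export
readSampleLabels <- function(labelsPath) {
    if (!file.exists(labelsPath))
        stop("cannot read labels file: ", labelsPath)
    df <- read.table(labelsPath, sep = "\t", header = FALSE,
                     colClasses = "character", quote = "")
    stats::setNames(df[[2]], trimws(df[[1]]))
}

#' Assemble a labelled expression container
#'
#' @param values numeric matrix, genes (or probes) by samples; row and
#'   column names required.
#' @param labels named vector mapping every sample (column) to
#'   case/control.
#' @return A \code{SummarizedExperiment} with assay \code{"expr"} and
#'   \code{colData$condition}.
#' @export
makeExpressionSet <- function(values, labels) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix needs row and column names")
    rownames(values) <- normalizeSymbol(rownames(values))
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene symbols; collapse probes first")
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
        stop("samples without labels: ", paste(missing, collapse = ", "))
    cond <- normalizeLabels(labels[colnames(values)])
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(values)))
}

#' Read a probe-to-gene annotation table
#'
#' Two-column TSV \code{probe<TAB>symbol}; probes with an empty symbol are
#' dropped. Probe ids must be unique per (probe, symbol) pair; a probe may
#' map to several symbols.
#'
#' @param path annotation TSV path.
#' @return data.frame with columns \code{probe}, \code{symbol}.
#' @export
readProbeAnnotation <- function(path) {
    if (!file.exists(path)) stop("cannot read probe annotation: ", path)
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = "character", quote = "")
    out <- data.frame(probe = trimws(df[[1]]),
                      symbol = normalizeSymbol(df[[2]]),
                      stringsAsFactors = FALSE)
    out <- out[nzchar(out$probe) & nzchar(out$symbol), , drop = FALSE]
    out[!duplicated(out), , drop = FALSE]
}

#' Collapse probe-level expression to gene level by averaging
#'
#' Each gene's expression per sample is the arithmetic mean over all probes
#' annotated to it; probes without an annotation are dropped, and a probe
#' annotated to several symbols contributes to each.
#'
#' @param raw numeric matrix, probes by samples, with probe rownames.
#' @param annotation data.frame as from \code{\link{readProbeAnnotation}},
#'   or a named character vector probe -> symbol.
#' @param labels optional named sample labels; when supplied the result is a
#'   \code{SummarizedExperiment}, otherwise a plain gene-by-sample matrix.
#' @return gene-level matrix or \code{SummarizedExperiment}.
#' @export
collapseProbes <- function(raw, annotation, labels = NULL) {
    if (is.character(annotation) && !is.null(names(annotation)))
        annotation <- data.frame(probe = names(annotation),
                                 symbol = normalizeSymbol(annotation),
                                 stringsAsFactors = FALSE)
    ann <- annotation[annotation$probe %in% rownames(raw) &
                      nzchar(annotation$symbol), , drop = FALSE]
    if (nrow(ann) == 0L)
        stop("no probe maps to a gene symbol")
    sub <- raw[ann$probe, , drop = FALSE]
    gene <- factor(ann$symbol)
    sums <- rowsum(sub, gene)
    counts <- as.vector(table(gene))
    m <- sums / counts
    m <- m[sort(rownames(m)), , drop = FALSE]
    if (is.null(labels)) m else makeExpressionSet(m, labels)
}

#' Read a GEO series-matrix style expression file
#'
#' Skips the \code{!}-prefixed header/metadata block, reads the matrix
#' between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} (or, failing those markers, all
#' non-\code{!} lines) with probe ids in the first column.
#'
#' @param path series-matrix TSV path.
#' @return numeric matrix, probes by samples.
#' @export
readSeriesMatrix <- function(path) {
    if (!file.exists(path)) stop("cannot read series matrix: ", path)
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    body <- if (length(beg) && length(end) && end[1] > beg[1])
        lines[(beg[1] + 1L):(end[1] - 1L)]
    else lines[!startsWith(lines, "!")]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 2L) stop("no matrix block found in ", path)
    con <- textConnection(body)
    on.exit(close(con))
    df <- read.table(con, sep = "\t", header = TRUE, row.names = 1,
                     check.names = FALSE, quote = "\"")
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    m
}

#' Read a drug-target interaction table
#'
#' TSV with columns \code{drug_id}, \code{drug_name}, \code{gene_symbol}
#' (header required). Records with an empty gene symbol are skipped with a
#' warning; (drug, target) pairs are deduplicated after symbol
#' normalisation.
#'
#' @param path drug-target TSV path.
#' @return data.frame with columns \code{drugId}, \code{drugName},
#'   \code{gene}.
#' @export
readDrugTargets <- function(path) {
    if (!file.exists(path)) stop("cannot read drug-target file: ", path)
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = "character", quote = "",
                     comment.char = "")
    need <- c("drug_id", "drug_name", "gene_symbol")
    if (!all(need %in% colnames(df)))
        stop("drug-target file must have columns: ",
             paste(need, collapse = ", "))
    out <- data.frame(drugId = trimws(df$drug_id),
                      drugName = trimws(df$drug_name),
                      gene = normalizeSymbol(df$gene_symbol),
                      stringsAsFactors = FALSE)
    empty <- !nzchar(out$gene) | !nzchar(out$drugId)
    if (any(empty))
        warning(sum(empty), " record(s) with empty drug id or gene symbol",
                " skipped")
    out <- out[!empty, , drop = FALSE]
    out[!duplicated(out[, c("drugId", "gene")]), , drop = FALSE]
}

#' Export a network in SIF format
#'
#' One line per edge: \code{source<TAB>relation<TAB>target}. Isolated nodes
#' are written as single-column lines, as Cytoscape expects.
#'
#' @param graph an \code{igraph}.
#' @param path output path.
#' @param relation interaction type written in the middle column.
#' @export
writeNetworkSIF <- function(graph, path, relation = "pp") {
    el <- igraph::as_edgelist(graph)
    lines <- character()
    if (nrow(el))
        lines <- paste(el[, 1], relation, el[, 2], sep = "\t")
    iso <- setdiff(igraph::V(graph)$name,
                   unique(c(el[, 1], el[, 2])))
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' Export a network in GraphML format
#'
#' Vertex attributes (e.g. \code{roleCategory}, \code{nodeType}) are
#' preserved.
#'
#' @param graph an \code{igraph}.
#' @param path output path.
#' @export
writeNetworkGraphML <- function(graph, path) {
    igraph::write_graph(graph, path, format = "graphml")
    invisible(path)
}
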