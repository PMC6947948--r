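#' @include triplet-network.R
NULL

.P_FLOOR <- 1e-300

## Split a labelled SummarizedExperiment into matrix + group indices.
exprParts <- function(se) {
    m <- SummarizedExperiment::assay(se, "expr")
    cond <- SummarizedExperiment::colData(se)$condition
    if (is.null(cond)) stop("expression object has no condition labels")
    list(mat = m,
         caseIdx = which(cond == "CASE"),
         ctrlIdx = which(cond == "CONTROL"))
}

## Vectorised two-sample t-test p-values over matrix rows.
## Degenerate rows (zero variance in both groups): p = 1 when the means
## agree, the floor value when they differ. Result floored at .P_FLOOR.
rowTTestP <- function(mat, caseIdx, ctrlIdx, test = c("student", "welch")) {
    test <- match.arg(test)
    n1 <- length(caseIdx); n2 <- length(ctrlIdx)
    if (n1 < 2L || n2 < 2L) stop("need >=2 samples per group for t-tests")
    x <- mat[, caseIdx, drop = FALSE]
    y <- mat[, ctrlIdx, drop = FALSE]
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowVarsM(x, m1); v2 <- rowVarsM(y, m2)
    if (test == "student") {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        sedd <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2, length(m1))
    } else {
        se2 <- v1 / n1 + v2 / n2
        sedd <- sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tstat <- (m1 - m2) / sedd
    p <- 2 * stats::pt(-abs(tstat), df)
    zero <- !is.finite(tstat)
    p[zero] <- ifelse(abs(m1[zero] - m2[zero]) < 1e-12, 1, .P_FLOOR)
    pmax(p, .P_FLOOR)
}

## Pearson correlations for row pairs (i, j) within one sample subset,
## vectorised via row standardisation. Constant rows correlate as 0.
rowPairPCC <- function(mat, idx, i, j) {
    sub <- mat[, idx, drop = FALSE]
    n <- ncol(sub)
    if (n < 3L) stop("need >=3 samples in a group for correlations")
    mu <- rowMeans(sub)
    sdv <- sqrt(rowVarsM(sub, mu))
    z <- (sub - mu) / sdv
    z[sdv < 1e-12, ] <- 0   # constant gene: define r = 0
    r <- rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE]) / (n - 1)
    pmin(pmax(r, -1), 1)
}

#' Differential-expression p-value for one gene
#'
#' Two-sided two-sample t-test (pooled-variance Student's by default,
#' Welch behind the \code{test} flag) comparing cases to controls. When the
#' pooled variance is zero the p-value is 1 for equal means and the floor
#' value \code{1e-300} for unequal means; all p-values are floored at
#' \code{1e-300} so downstream score products never underflow to exact 0.
#'
#' @param se labelled expression \code{SummarizedExperiment}.
#' @param gene gene symbol (must be present).
#' @param test \code{"student"} or \code{"welch"}.
#' @return p-value in (0, 1].
#' @export
genePValue <- function(se, gene, test = c("student", "welch")) {
    gene <- normalizeSymbol(gene)
    ep <- exprParts(se)
    if (!gene %in% rownames(ep$mat)) stop("gene not in expression data: ",
                                          gene)
    unname(rowTTestP(ep$mat[gene, , drop = FALSE], ep$caseIdx, ep$ctrlIdx,
                     test = match.arg(test)))
}

#' Within-group Pearson correlation of two genes
#'
#' @param se labelled expression \code{SummarizedExperiment}.
#' @param geneX,geneY gene symbols.
#' @param group \code{"CASE"} or \code{"CONTROL"}.
#' @return correlation in [-1, 1]; 0 (with a warning) when either gene is
#'   constant within the group.
#' @export
pairPCC <- function(se, geneX, geneY, group = c("CASE", "CONTROL")) {
    group <- match.arg(group)
    geneX <- normalizeSymbol(geneX); geneY <- normalizeSymbol(geneY)
    ep <- exprParts(se)
    idx <- if (group == "CASE") ep$caseIdx else ep$ctrlIdx
    for (g in c(geneX, geneY))
        if (!g %in% rownames(ep$mat))
            stop("gene not in expression data: ", g)
    if (length(idx) < 3L) stop("need >=3 samples in group ", group)
    x <- ep$mat[geneX, idx]; y <- ep$mat[geneY, idx]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        warning("constant expression vector; correlation set to 0")
        return(0)
    }
    stats::cor(x, y)
}

## Core scorer shared by the observed pass and every permutation pass:
## returns scoreDif/scorePCC (plus components) for all triplets at once.
scoreCore <- function(mat, caseIdx, ctrlIdx, ii, jj, kk, test) {
    p <- rowTTestP(mat, caseIdx, ctrlIdx, test = test)
    pairI <- c(ii, ii, jj)
    pairJ <- c(jj, kk, kk)
    rCase <- rowPairPCC(mat, caseIdx, pairI, pairJ)
    rCtrl <- rowPairPCC(mat, ctrlIdx, pairI, pairJ)
    nT <- length(ii)
    d <- matrix(rCase - rCtrl, nrow = nT)      # columns: im-in, im-d, in-d
    p <- unname(p)
    list(scoreDif = p[ii] * p[jj] * p[kk],
         scorePCC = unname(abs(d[, 1] * d[, 2] * d[, 3])),
         p = cbind(pImmune = p[ii], pInflammation = p[jj], pDisease = p[kk]),
         rCase = matrix(rCase, nrow = nT,
                        dimnames = list(NULL, c("pccCaseImIn", "pccCaseImD",
                                                "pccCaseInD"))),
         rCtrl = matrix(rCtrl, nrow = nT,
                        dimnames = list(NULL, c("pccCtrlImIn", "pccCtrlImD",
                                                "pccCtrlInD"))))
}

## Map triplet symbols to row indices of the expression matrix; triplets
## with absent genes or genes carrying missing values are dropped with a
## message.
tripletIndices <- function(tripletSet, mat) {
    el <- triplets(tripletSet)
    ok <- rowSums(is.na(mat)) == 0L
    usable <- rownames(mat)[ok]
    keep <- el$immune %in% usable & el$inflammation %in% usable &
        el$disease %in% usable
    if (any(!keep))
        message(sum(!keep), " triplet(s) dropped: gene absent from the ",
                "expression data or carrying missing values")
    el <- el[keep, , drop = FALSE]
    list(elements = el,
         ii = match(el$immune, rownames(mat)),
         jj = match(el$inflammation, rownames(mat)),
         kk = match(el$disease, rownames(mat)))
}

#' Score triplets for dysregulation
#'
#' For each triplet computes \code{scoreDif}, the product of the three
#' per-gene case-vs-control t-test p-values (small = coordinated
#' differential expression), and \code{scorePCC}, the absolute product of
#' the three between-group Pearson-correlation differences
#' (large = correlation rewiring). Triplets whose genes are missing from
#' the expression data are dropped with a message.
#'
#' @param se labelled expression \code{SummarizedExperiment}.
#' @param tripletSet a \linkS4class{TripletSet}.
#' @param test t-test flavour, \code{"student"} (default) or
#'   \code{"welch"}.
#' @return A \code{DataFrame} with the triplet columns, the three p-values,
#'   the six group-wise pair correlations and the two scores.
#' @export
scoreTriplets <- function(se, tripletSet, test = c("student", "welch")) {
    test <- match.arg(test)
    ep <- exprParts(se)
    ti <- tripletIndices(tripletSet, ep$mat)
    if (nrow(ti$elements) == 0L)
        stop("no scorable triplets (all dropped)")
    sc <- scoreCore(ep$mat, ep$caseIdx, ep$ctrlIdx,
                    ti$ii, ti$jj, ti$kk, test)
    DataFrame(ti$elements, sc$p, sc$rCase, sc$rCtrl,
              scoreDif = sc$scoreDif, scorePCC = sc$scorePCC)
}

#' Combine the two dysregulation scores by equally weighted ranks
#'
#' \code{rankDif} ranks triplets by descending dysregulation on
#' \code{scoreDif} (the smallest p-value product receives the largest rank
#' value M), \code{rankPCC} ranks ascending on \code{scorePCC} (the largest
#' correlation change receives rank M); ties get average (fractional)
#' ranks. The final score is the mean of the two ranks, so a higher final
#' score always means stronger dysregulation.
#'
#' @param scores \code{DataFrame} from \code{\link{scoreTriplets}}.
#' @return the input with \code{rankDif}, \code{rankPCC} and
#'   \code{finalScore} columns added.
#' @export
combineRanks <- function(scores) {
    if (nrow(scores) < 1L) stop("need >=1 scored triplet")
    scores$rankDif <- rank(-scores$scoreDif, ties.method = "average")
    scores$rankPCC <- rank(scores$scorePCC, ties.method = "average")
    scores$finalScore <- (scores$rankDif + scores$rankPCC) / 2
    scores
}

## Rank values x within a reference vector v, matching rank()'s average-tie
## convention: ascending = #\{v < x\} + (#\{v == x\} + 1)/2. Vectorised via
## findInterval on the sorted reference.
rankWithin <- function(v, x, descending = FALSE) {
    if (descending) { v <- -v; x <- -x }
    sv <- sort(v)
    below <- findInterval(x, sv, left.open = TRUE)   # #{v < x} + ties<=...
    upto <- findInterval(x, sv)                      # #{v <= x}
    nBelow <- below
    nTies <- upto - below
    nBelow + (nTies + 1) / 2
}

#' Permutation p-values for triplet final scores
#'
#' Shuffles the case/control labels \code{nPerm} times (group sizes
#' preserved) and rescores all triplets within each permutation. Each
#' permuted pair of scores is converted to a final ranking score and
#' compared with the triplet's observed final score; the add-one empirical
#' p-value is
#' \code{permP = (1 + #\{permuted finalScore >= observed\}) / (1 + nPerm)}
#' per triplet, so \code{permP > 0} always.
#'
#' Two ranking frames for the permuted scores are available.
#' \code{"observed"} (default) ranks each triplet's permuted
#' \code{scoreDif}/\code{scorePCC} against the observed cohort's score
#' distributions, asking how extreme the triplet's final ranking score
#' would look under random labels while the ranking frame is held fixed;
#' it is calibrated under the null and retains power when a sizeable part
#' of the cohort is truly dysregulated. \code{"permuted"} jointly re-ranks
#' all triplets within each permuted cohort; because label shuffling
#' removes the signal from every triplet at once, the permuted ranks are
#' nearly exchangeable across the cohort, which bounds each triplet's
#' attainable p-value by its observed normalized rank and caps the number
#' of significant calls at roughly \code{alpha} times the cohort size.
#'
#' @param se labelled expression \code{SummarizedExperiment}.
#' @param tripletSet a \linkS4class{TripletSet}.
#' @param nPerm number of label permutations (>= 1; the field's customary
#'   choice is 1000).
#' @param seed integer seed; fixed seeds give bit-reproducible p-values.
#' @param test t-test flavour.
#' @param rankFrame \code{"observed"} or \code{"permuted"}; see Details.
#' @return A \code{DataFrame} as from \code{\link{combineRanks}} with a
#'   \code{permP} column added.
#' @export
permutationPValues <- function(se, tripletSet, nPerm = 1000, seed = 1L,
                               test = c("student", "welch"),
                               rankFrame = c("observed", "permuted")) {
    test <- match.arg(test)
    rankFrame <- match.arg(rankFrame)
    if (nPerm < 1L) stop("nPerm must be >= 1")
    ep <- exprParts(se)
    ti <- tripletIndices(tripletSet, ep$mat)
    if (nrow(ti$elements) == 0L) stop("no scorable triplets")
    obs <- scoreCore(ep$mat, ep$caseIdx, ep$ctrlIdx,
                     ti$ii, ti$jj, ti$kk, test)
    obsScores <- DataFrame(ti$elements, obs$p, obs$rCase, obs$rCtrl,
                           scoreDif = obs$scoreDif, scorePCC = obs$scorePCC)
    obsScores <- combineRanks(obsScores)
    n1 <- length(ep$caseIdx)
    allIdx <- c(ep$caseIdx, ep$ctrlIdx)
    exceed <- integer(nrow(obsScores))
    set.seed(as.integer(seed))
    for (b in seq_len(nPerm)) {
        perm <- sample(allIdx)
        ca <- perm[seq_len(n1)]
        co <- perm[(n1 + 1L):length(perm)]
        sc <- scoreCore(ep$mat, ca, co, ti$ii, ti$jj, ti$kk, test)
        pf <- if (rankFrame == "permuted") {
            (rank(-sc$scoreDif, ties.method = "average") +
             rank(sc$scorePCC, ties.method = "average")) / 2
        } else {
            (rankWithin(obsScores$scoreDif, sc$scoreDif,
                        descending = TRUE) +
             rankWithin(obsScores$scorePCC, sc$scorePCC)) / 2
        }
        exceed <- exceed + (pf >= obsScores$finalScore)
    }
    obsScores$permP <- (1 + exceed) / (1 + nPerm)
    obsScores
}

#' Select significantly dysregulated triplets
#'
#' Keeps triplets with \code{permP < alpha} (strict, no multiplicity
#' correction) and builds the gene subnetwork induced by their triangles.
#'
#' @param scores \code{DataFrame} from \code{\link{permutationPValues}}.
#' @param catalog \linkS4class{GeneRoleCatalog} for node role categories.
#' @param alpha significance threshold (default 0.05).
#' @return A \linkS4class{DysregulatedNetwork}.
#' @export
selectDysregulated <- function(scores, catalog, alpha = 0.05) {
    if (is.null(scores$permP)) stop("scores lack permutation p-values")
    keep <- scores$permP < alpha
    rec <- scores[keep, , drop = FALSE]
    ts <- TripletSet(rec$immune, rec$inflammation, rec$disease)
    new("DysregulatedNetwork", records = rec,
        graph = buildTripletNetwork(ts, catalog), alpha = alpha)
}

#' @describeIn selectDysregulated significant score records.
#' @param x a \code{DysregulatedNetwork}.
#' @param ... unused.
#' @export
setMethod("records", "DysregulatedNetwork", function(x, ...) x@records)

#' @describeIn selectDysregulated induced gene subnetwork (\code{igraph}).
#' @export
setMethod("networkGraph", "DysregulatedNetwork", function(x, ...) x@graph)

setMethod("show", "DysregulatedNetwork", function(object) {
    cat(sprintf(
        "DysregulatedNetwork: %d triplet(s), %d node(s), %d edge(s), alpha = %g\n",
        nrow(object@records), igraph::vcount(object@graph),
        igraph::ecount(object@graph), object@alpha))
})

#' Rank concordance of the selected triplets
#'
#' Percentage of selected triplets whose global rank (by descending
#' \code{finalScore}, average ranks for ties) is at most the number of
#' selected triplets — i.e. how many of the significant triplets sit in the
#' top-|selected| block of the full ranking.
#'
#' @param scores full score \code{DataFrame} with \code{finalScore}.
#' @param selected the selected subset: a \code{DysregulatedNetwork}, a
#'   score \code{DataFrame}, or a logical/integer index into \code{scores}.
#' @return percentage in [0, 100].
#' @export
rankConcordance <- function(scores, selected) {
    if (is(selected, "DysregulatedNetwork")) selected <- records(selected)
    if (is.logical(selected) || is.numeric(selected)) {
        selRows <- selected
    } else {
        key <- function(d) paste(d$immune, d$inflammation, d$disease,
                                 sep = "\r")
        selRows <- key(scores) %in% key(selected)
    }
    sel <- which(if (is.logical(selRows)) selRows else
        seq_len(nrow(scores)) %in% selRows)
    if (length(sel) == 0L) stop("empty selection")
    globalRank <- rank(-scores$finalScore, ties.method = "average")
    100 * sum(globalRank[sel] <= length(sel)) / length(sel)
}
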