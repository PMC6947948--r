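## Internal helpers shared across modules.

## Uppercase + strip surrounding whitespace; the only symbol normalisation
## applied anywhere (no alias resolution).
normalizeSymbol <- function(x) toupper(trimws(as.character(x)))

## Derived per-stage seed, kept inside 32-bit integer range so toggling one
## pipeline stage never perturbs another stage's stream.
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647L)
}

## Row means / unbiased row variances on a plain matrix.
rowVarsM <- function(m, means = rowMeans(m)) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    rowSums((m - means)^2) / (n - 1)
}

## Trapezoidal area under y(x).
trapezoidArea <- function(x, y) {
    n <- length(x)
    sum(diff(x) * (y[-1] + y[-n]) / 2)
}

## Condition labels used throughout: factor with levels CASE, CONTROL.
normalizeLabels <- function(labels) {
    lab <- toupper(trimws(as.character(labels)))
    lab[lab %in% c("CASE", "DISEASE", "PATIENT", "MGN", "TUMOR")] <- "CASE"
    lab[lab %in% c("CONTROL", "NORMAL", "CTRL", "HEALTHY")] <- "CONTROL"
    bad <- setdiff(unique(lab), c("CASE", "CONTROL"))
    if (length(bad))
        stop("unrecognised sample labels: ", paste(bad, collapse = ", "))
    factor(lab, levels = c("CASE", "CONTROL"))
}
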