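## Internal helpers shared across modules.

## Evaluate `code` under a given RNG seed, restoring the caller's RNG state
## afterwards. seed = NULL evaluates as-is.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(code)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    code
}

## Derive a stream of per-task seeds from one master seed (kept < 2^31).
.deriveSeeds <- function(seed, n) {
    .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Pearson correlation with the conventions used throughout: identical
## vectors (including length 1) give r = 1; otherwise zero variance in
## either vector makes r undefined and NA is returned.
.pearson <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length", call. = FALSE)
    x <- unname(x); y <- unname(y)
    if (isTRUE(all.equal(x, y, tolerance = 1e-12, scale = 1)))
        return(1)
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
        return(NA_real_)
    stats::cor(x, y)
}

## Normalize a support argument (character labels, list from
## parseChainLabel, or FADistribution) to a sorted unique chain list.
.asSupport <- function(support) {
    if (is(support, "FADistribution"))
        return(list(carbons = support@carbons,
                    doubleBonds = support@doubleBonds))
    if (is.character(support))
        support <- parseChainLabel(support)
    stopifnot(is.list(support),
              all(c("carbons", "doubleBonds") %in% names(support)))
    key <- .cdKey(support$carbons, support$doubleBonds)
    if (anyDuplicated(key))
        stop("duplicated chains in support", call. = FALSE)
    ord <- order(support$carbons, support$doubleBonds)
    list(carbons = as.integer(support$carbons[ord]),
         doubleBonds = as.integer(support$doubleBonds[ord]))
}

.degenerateError <- function(msg) {
    stop(errorCondition(msg, class = c("clremodel_degenerate", "error")))
}
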