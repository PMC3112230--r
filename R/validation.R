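## Significance machinery for the positional and proportional models:
## repeated 4-fold cross-validation over CL peaks, a label-permutation
## null for the positional models, an empirical donor-permutation null for
## the proportional model, and the IDD-vs-IID comparison.

## Random partition of n items into `folds` subsets with sizes differing
## by at most 1.
.makeFolds <- function(n, folds) {
    sample(rep(seq_len(folds), length.out = n))
}

.subProfile <- function(observed, idx) {
    new("CLProfile",
        totalCarbons = observed@totalCarbons[idx],
        totalDoubleBonds = observed@totalDoubleBonds[idx],
        values = observed@values[idx],
        kind = "predicted")   # subset values need not sum to 1
}

.fitModel <- function(observed, support, model, ...) {
    if (model == "IID") suppressWarnings(fitIID(observed, support, ...))
    else suppressWarnings(fitIDD(observed, support, ...))
}

#' Cross-validate a positional model over CL peaks
#'
#' Per run, the observed CL peaks are randomly partitioned into
#' \code{folds} disjoint subsets of (as near as possible) equal size. Each
#' fold in turn is held out: the model is fit to the remaining peaks only
#' and its predicted values at the held-out peak keys are recorded. The
#' merged held-out predictions for all folds are compared with the
#' observed values by one Pearson correlation per run. Held-out
#' predictions are compared unnormalized; Pearson correlation is
#' location/scale invariant, so the merged comparison is well defined
#' without renormalizing the partial fits.
#'
#' @param observed observed [CLProfile-class].
#' @param support candidate chain types (see [fitIID()]).
#' @param model \code{"IID"} (default) or \code{"IDD"}.
#' @param folds number of folds (default 4).
#' @param runs number of independent repetitions, each with a fresh random
#'   partition (default 3).
#' @param seed integer seed (required; partitions are reproducible).
#' @return A [CVResult-class] holding the per-run correlations;
#'   \code{cvCorrelations()} accesses them.
#' @examples
#' fa <- FADistribution(c("16:0" = 0.3, "18:1" = 0.45, "18:2" = 0.25))
#' obs <- peakDistributionIID(fa); obs@kind <- "observed"
#' cv <- crossValidateCL(obs, chainLabels(fa), seed = 1)
#' mean(cvCorrelations(cv))
#' @export
crossValidateCL <- function(observed, support, model = c("IID", "IDD"),
                            folds = 4, runs = 3, seed) {
    model <- match.arg(model)
    stopifnot(is(observed, "CLProfile"))
    if (missing(seed) || is.null(seed))
        stop("'seed' is required for reproducible partitions")
    n <- length(observed@values)
    if (folds > n)
        stop(sprintf("folds (%d) exceeds the number of peaks (%d)",
                     folds, n))
    runSeeds <- .deriveSeeds(seed, runs)
    r <- vapply(seq_len(runs), function(run) {
        fold <- .withSeed(runSeeds[run], .makeFolds(n, folds))
        merged <- numeric(n)
        for (f in seq_len(folds)) {
            test <- which(fold == f)
            train <- which(fold != f)
            fit <- .fitModel(.subProfile(observed, train), support, model)
            predAll <- if (model == "IID")
                peakDistributionIID(faDistributions(fit)[[1]])
            else peakDistributionIDD(faDistributions(fit)$sn1,
                                     faDistributions(fit)$sn2)
            keyAll <- .cdKey(predAll@totalCarbons, predAll@totalDoubleBonds)
            keyTest <- .cdKey(observed@totalCarbons[test],
                              observed@totalDoubleBonds[test])
            v <- predAll@values[match(keyTest, keyAll)]
            v[is.na(v)] <- 0
            merged[test] <- v
        }
        .pearson(merged, observed@values)
    }, numeric(1))
    new("CVResult", r = r, model = model, folds = as.integer(folds),
        runs = as.integer(runs), seed = as.integer(seed))
}

## Welch two-sample t-test that tolerates (near-)constant inputs:
## both groups degenerate -> classed error; otherwise fall back to the
## exact-equality convention.
.welch <- function(x, y, alternative) {
    if (anyNA(x) || anyNA(y))
        .degenerateError(
            "degenerate comparison: undefined correlation(s) (zero-variance data)")
    degx <- stats::sd(x) < 1e-12
    degy <- stats::sd(y) < 1e-12
    if (degx && degy) {
        if (abs(mean(x) - mean(y)) < 1e-12)
            .degenerateError(
                "degenerate comparison: both groups have zero variance and equal means")
        .degenerateError(
            "degenerate comparison: both groups have zero variance")
    }
    stats::t.test(x, y, alternative = alternative, var.equal = FALSE)$p.value
}

#' Label-permutation significance test for a positional model
#'
#' Tests whether the cross-validated fit of the positional model reflects
#' real structure linking CL peak identities (total carbons/double bonds)
#' to their concentrations. The null datasets permute the concentration
#' values across the peak keys, destroying that link while preserving the
#' value distribution. Cross-validation ([crossValidateCL()]) is run on
#' the real data and on each permuted dataset; a one-tailed Welch t-test
#' compares the real per-run correlations against the pooled permuted
#' ones (real greater).
#'
#' @inheritParams crossValidateCL
#' @param nPermDatasets number of independently permuted datasets
#'   (default 3); each is cross-validated with \code{runs} runs.
#' @return A [PermutationResult-class]; \code{observed} holds the real
#'   per-run CV correlations and \code{null} the pooled permuted ones.
#' @examples
#' fa <- FADistribution(c("16:0" = 0.3, "18:1" = 0.45, "18:2" = 0.25))
#' obs <- peakDistributionIID(fa); obs@kind <- "observed"
#' pValue(labelPermutationTest(obs, chainLabels(fa), seed = 1))
#' @export
labelPermutationTest <- function(observed, support, model = c("IID", "IDD"),
                                 nPermDatasets = 3, folds = 4, runs = 3,
                                 seed) {
    model <- match.arg(model)
    if (missing(seed) || is.null(seed))
        stop("'seed' is required")
    seeds <- .deriveSeeds(seed, 2L * nPermDatasets + 1L)
    real <- cvCorrelations(
        crossValidateCL(observed, support, model, folds, runs, seeds[1L]))
    null <- unlist(lapply(seq_len(nPermDatasets), function(i) {
        perm <- .withSeed(seeds[2L * i],
                          sample(seq_along(observed@values)))
        shuffled <- new("CLProfile",
                        totalCarbons = observed@totalCarbons,
                        totalDoubleBonds = observed@totalDoubleBonds,
                        values = observed@values[perm],
                        kind = observed@kind)
        cvCorrelations(crossValidateCL(shuffled, support, model, folds,
                                       runs, seeds[2L * i + 1L]))
    }))
    p <- .welch(real, null, alternative = "greater")
    new("PermutationResult",
        statistic = "cross-validated Pearson r",
        observed = real, null = null, pValue = p,
        method = sprintf(
            "one-tailed Welch t-test, %d real vs %d label-permuted CV runs",
            length(real), length(null)))
}

#' Donor-permutation significance test for the proportional model
#'
#' Assesses whether the proportional-incorporation fit
#' ([fitProportional()]) captures real correspondence between the CL
#' composition and the donor pools. For each of \code{nPerm} null
#' datasets, every donor pool's probabilities are independently shuffled
#' across the chain labels of the aligned support and the weights are
#' refit; the Pearson correlation of each null fit is recorded. The
#' empirical p-value uses the add-one correction
#' \code{(1 + #\{null r >= observed r\}) / (nPerm + 1)}, so it is never
#' exactly zero.
#'
#' @param clFA [FADistribution-class], the CL chain composition (IID fit).
#' @param donors named list of donor pools as in [fitProportional()].
#' @param nPerm number of permuted datasets (default 10000).
#' @param seed integer seed (required).
#' @return A [PermutationResult-class] whose \code{observed} slot is the
#'   real fit's Pearson correlation.
#' @examples
#' pg <- FADistribution(c("16:0" = 0.6, "18:1" = 0.4))
#' pc <- FADistribution(c("18:2" = 0.8, "20:4" = 0.2))
#' cl <- FADistribution(c("16:0" = 0.3, "18:1" = 0.2, "18:2" = 0.4,
#'                        "20:4" = 0.1))
#' donorPermutationTest(cl, list(PG = pg, PC_sn2 = pc), nPerm = 99,
#'                      seed = 1)
#' @export
donorPermutationTest <- function(clFA, donors, nPerm = 10000, seed) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (missing(seed) || is.null(seed))
        stop("'seed' is required")
    obsFit <- suppressWarnings(fitProportional(clFA, donors))
    al <- .alignChains(clFA, donors)
    nChain <- nrow(al$D)
    obsR <- pearsonR(obsFit)
    nullR <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
        Dp <- al$D
        for (j in seq_len(ncol(Dp)))
            Dp[, j] <- Dp[sample.int(nChain), j]
        w <- .simplexLsq(Dp, al$y)$w
        .pearson(as.vector(Dp %*% w), al$y)
    }, numeric(1)))
    exceed <- sum(!is.na(nullR) & nullR >= obsR - 1e-12)
    p <- (1 + exceed) / (nPerm + 1)
    new("PermutationResult",
        statistic = "proportional-fit Pearson r",
        observed = obsR, null = nullR, pValue = p,
        method = sprintf(
            "empirical p over %d donor-composition permutations (add-one corrected; raw exceedance count %d)",
            nPerm, exceed))
}

#' Compare IDD against IID by cross-validation
#'
#' Runs the repeated 4-fold cross-validation protocol for both positional
#' models (independent random splits) and compares the two sets of per-run
#' correlations with a two-sided Welch t-test. A small p-value with higher
#' IDD correlations indicates that distinguishing the sn-1/sn-1' from the
#' sn-2/sn-2' positions genuinely improves predictions.
#'
#' @inheritParams crossValidateCL
#' @return A list with \code{pValue}, and the two [CVResult-class] objects
#'   \code{cvIID} and \code{cvIDD}. Identical score sets give
#'   \code{pValue = 1}.
#' @examples
#' fa <- FADistribution(c("16:0" = 0.3, "18:1" = 0.45, "18:2" = 0.25))
#' obs <- peakDistributionIID(fa); obs@kind <- "observed"
#' compareIDDvsIID(obs, chainLabels(fa), seed = 1)$pValue
#' @export
compareIDDvsIID <- function(observed, support, folds = 4, runs = 3, seed) {
    if (missing(seed) || is.null(seed))
        stop("'seed' is required")
    seeds <- .deriveSeeds(seed, 2L)
    cvIID <- crossValidateCL(observed, support, "IID", folds, runs,
                             seeds[1L])
    cvIDD <- crossValidateCL(observed, support, "IDD", folds, runs,
                             seeds[2L])
    x <- cvCorrelations(cvIID); y <- cvCorrelations(cvIDD)
    p <- if (isTRUE(all.equal(x, y, tolerance = 1e-12, scale = 1))) 1
         else tryCatch(.welch(x, y, alternative = "two.sided"),
                       clremodel_degenerate = function(e) 1)
    list(pValue = p, cvIID = cvIID, cvIDD = cvIDD)
}
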