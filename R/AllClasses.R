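#' @import methods
NULL

## Normalization tolerance used by all validity checks (probability vectors
## must sum to 1 within this).
.TOL_NORM <- 1e-9

## Integer key for a (carbons, double-bonds) pair. Double-bond counts are
## bounded by 4 chains x 6 double bonds = 24 << 64, so the key is unique.
.cdKey <- function(carbons, doubleBonds) carbons * 64L + doubleBonds

.cdLabel <- function(carbons, doubleBonds) paste0(carbons, ":", doubleBonds)

#' FADistribution: a probability distribution over acyl chain types
#'
#' Represents a fatty-acid (FA) composition as a probability vector over
#' acyl chain types, each identified by its carbon count and number of
#' double bonds (e.g. \code{18:1}). Used both for the inferred per-position
#' CL chain distribution and for acyl donor pools (PC sn-2, PE sn-2, PG,
#' acyl CoA).
#'
#' @slot carbons integer vector of acyl carbon counts, one per chain.
#' @slot doubleBonds integer vector of double-bond counts, one per chain.
#' @slot probs numeric vector of probabilities, one per chain; nonnegative
#'   and summing to 1 within \code{1e-9}.
#'
#' @section Validity:
#' Chains must be unique, satisfy \code{carbons >= 1},
#' \code{0 <= doubleBonds < carbons}, and the probability vector must be
#' nonnegative and normalized. Zero-probability chains are allowed (they are
#' retained for reporting but skipped in enumeration).
#'
#' @seealso [FADistribution()] for construction, [peakDistributionIID()]
#' @exportClass FADistribution
setClass("FADistribution",
         representation(carbons = "integer",
                        doubleBonds = "integer",
                        probs = "numeric"))

setValidity("FADistribution", function(object) {
    n <- length(object@probs)
    if (length(object@carbons) != n || length(object@doubleBonds) != n)
        return("carbons, doubleBonds and probs must have equal length")
    if (n == 0L)
        return("empty chain support")
    if (any(object@carbons < 1L))
        return("chain carbons must be >= 1")
    if (any(object@doubleBonds < 0L))
        return("double bonds must be >= 0")
    if (any(object@doubleBonds >= object@carbons))
        return("double bonds must be < carbons")
    if (anyDuplicated(.cdKey(object@carbons, object@doubleBonds)))
        return("duplicated chain types in support")
    if (any(object@probs < 0))
        return("chain probabilities must be nonnegative")
    if (abs(sum(object@probs) - 1) > .TOL_NORM)
        return(sprintf("chain probabilities must sum to 1 (got %.12g)",
                       sum(object@probs)))
    TRUE
})

#' Construct an FADistribution
#'
#' @param probs named numeric vector of probabilities; names are chain
#'   labels such as \code{"18:1"} (ASCII colon or the Unicode ratio
#'   character). Alternatively an unnamed numeric vector together with
#'   \code{labels}.
#' @param labels optional character vector of chain labels when
#'   \code{probs} is unnamed.
#' @param normalize logical; if \code{TRUE}, rescale \code{probs} to sum
#'   to 1 (useful when passing raw concentrations). Default \code{FALSE}.
#'
#' @return An [FADistribution-class] object with the support sorted by
#'   carbons, then double bonds.
#'
#' @examples
#' FADistribution(c("18:1" = 0.5, "18:2" = 0.5))
#' FADistribution(c(2, 2), labels = c("16:0", "18:1"), normalize = TRUE)
#' @export
FADistribution <- function(probs, labels = names(probs), normalize = FALSE) {
    if (is.null(labels))
        stop("chain labels are required (names of 'probs' or 'labels=')")
    ch <- parseChainLabel(labels)
    p <- as.numeric(probs)
    if (normalize) {
        s <- sum(p)
        if (s <= 0) stop("cannot normalize: nonpositive total")
        p <- p / s
    }
    ord <- order(ch$carbons, ch$doubleBonds)
    new("FADistribution",
        carbons = ch$carbons[ord],
        doubleBonds = ch$doubleBonds[ord],
        probs = p[ord])
}

#' CLProfile: a distribution over cardiolipin mass peaks
#'
#' A cardiolipin (CL) mass peak is identified by the total number of acyl
#' carbons and total double bonds over the four chains (e.g. \code{72:8}).
#' A \code{CLProfile} holds nonnegative values (probabilities, or model
#' mass) over an ordered set of peaks. Observed profiles are normalized;
#' predicted profiles restricted to a measured peak set may sum to less
#' than 1, because model mass can fall on unmeasured peaks.
#'
#' @slot totalCarbons integer vector, total carbons per peak.
#' @slot totalDoubleBonds integer vector, total double bonds per peak.
#' @slot values numeric vector of nonnegative peak values.
#' @slot kind character, \code{"observed"} or \code{"predicted"}. Observed
#'   profiles must sum to 1 within \code{1e-9}; predicted profiles may sum
#'   to at most \code{1 + 1e-9}.
#'
#' @exportClass CLProfile
setClass("CLProfile",
         representation(totalCarbons = "integer",
                        totalDoubleBonds = "integer",
                        values = "numeric",
                        kind = "character"))

setValidity("CLProfile", function(object) {
    n <- length(object@values)
    if (length(object@totalCarbons) != n || length(object@totalDoubleBonds) != n)
        return("peak keys and values must have equal length")
    if (n == 0L)
        return("empty peak set")
    if (!object@kind %in% c("observed", "predicted"))
        return("kind must be 'observed' or 'predicted'")
    if (anyDuplicated(.cdKey(object@totalCarbons, object@totalDoubleBonds)))
        return("duplicated peak keys")
    if (any(object@values < -.TOL_NORM))
        return("peak values must be nonnegative")
    tot <- sum(object@values)
    if (object@kind == "observed" && abs(tot - 1) > .TOL_NORM)
        return(sprintf("observed profile must sum to 1 (got %.12g)", tot))
    if (object@kind == "predicted" && tot > 1 + .TOL_NORM)
        return(sprintf("predicted profile mass exceeds 1 (got %.12g)", tot))
    TRUE
})

#' Construct a CLProfile
#'
#' @param values named numeric vector of peak values; names are peak labels
#'   such as \code{"72:8"} (total carbons : total double bonds), or an
#'   unnamed vector together with \code{labels}.
#' @param labels optional character vector of peak labels.
#' @param kind \code{"observed"} (must be normalized) or \code{"predicted"}.
#' @param normalize logical; rescale values to sum to 1 before validation.
#'
#' @return A [CLProfile-class] with peaks sorted by total carbons, then
#'   total double bonds.
#' @examples
#' CLProfile(c("72:8" = 0.6, "72:7" = 0.4))
#' @export
CLProfile <- function(values, labels = names(values), kind = "observed",
                      normalize = FALSE) {
    if (is.null(labels))
        stop("peak labels are required (names of 'values' or 'labels=')")
    pk <- .parsePeakLabel(labels)
    v <- as.numeric(values)
    if (normalize) {
        s <- sum(v)
        if (s <= 0) stop("cannot normalize: nonpositive total")
        v <- v / s
    }
    ord <- order(pk$carbons, pk$doubleBonds)
    new("CLProfile",
        totalCarbons = pk$carbons[ord],
        totalDoubleBonds = pk$doubleBonds[ord],
        values = v[ord],
        kind = kind)
}

#' SampleDataset: one sample's normalized lipidomic measurements
#'
#' Bundles a sample's replicate-averaged CL mass-peak profile with its acyl
#' donor pools. Donor classes are \code{PG}, \code{PC_sn2}, \code{PE_sn2}
#' and optionally \code{AC} (acyl CoA); PC/PE pools carry only sn-2 chains.
#'
#' @slot sampleId character scalar.
#' @slot clProfile observed [CLProfile-class].
#' @slot donorPools named list of [FADistribution-class] donor pools.
#' @slot nReplicates integer, number of replicates averaged.
#'
#' @exportClass SampleDataset
setClass("SampleDataset",
         representation(sampleId = "character",
                        clProfile = "CLProfile",
                        donorPools = "list",
                        nReplicates = "integer"))

setValidity("SampleDataset", function(object) {
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    if (length(object@donorPools) < 1L)
        return("at least one donor pool is required")
    if (is.null(names(object@donorPools)) ||
        !all(names(object@donorPools) %in% .DONOR_CLASSES))
        return(paste("donor pool names must be among:",
                     paste(.DONOR_CLASSES, collapse = ", ")))
    if (!all(vapply(object@donorPools, is, TRUE, "FADistribution")))
        return("donor pools must be FADistribution objects")
    if (object@clProfile@kind != "observed")
        return("clProfile must be an observed profile")
    if (object@nReplicates < 1L)
        return("nReplicates must be >= 1")
    TRUE
})

.DONOR_CLASSES <- c("PG", "PC_sn2", "PE_sn2", "AC")

#' CLFitResult: result of an IID or IDD positional-model fit
#'
#' @slot model \code{"IID"} or \code{"IDD"}.
#' @slot fa list of one ([FADistribution-class]; IID) or two (IDD: sn-1/sn-1'
#'   then sn-2/sn-2') fitted chain distributions.
#' @slot observed the observed [CLProfile-class] the fit was run against.
#' @slot predicted predicted [CLProfile-class] restricted to the observed
#'   peak set.
#' @slot error sum of squared deviations over the observed peak set.
#' @slot pearsonR Pearson correlation between predicted and observed peak
#'   values (\code{NA} when undefined).
#' @slot unassignedMass model probability mass on reachable peaks absent
#'   from the observed peak set (diagnostic; never renormalized away).
#' @slot unreachablePeaks character labels of observed peaks not reachable
#'   from the chain support (each contributes its squared observed value to
#'   the error).
#' @slot convergence list of optimizer diagnostics.
#' @exportClass CLFitResult
setClass("CLFitResult",
         representation(model = "character",
                        fa = "list",
                        observed = "CLProfile",
                        predicted = "CLProfile",
                        error = "numeric",
                        pearsonR = "numeric",
                        unassignedMass = "numeric",
                        unreachablePeaks = "character",
                        convergence = "list"))

setValidity("CLFitResult", function(object) {
    if (!object@model %in% c("IID", "IDD"))
        return("model must be 'IID' or 'IDD'")
    if (object@model == "IID" && length(object@fa) != 1L)
        return("IID fit must carry exactly one FA distribution")
    if (object@model == "IDD" && length(object@fa) != 2L)
        return("IDD fit must carry exactly two FA distributions")
    if (object@error < -1e-12)
        return("error must be nonnegative")
    if (!is.na(object@pearsonR) &&
        (object@pearsonR < -1 - 1e-9 || object@pearsonR > 1 + 1e-9))
        return("pearsonR must lie in [-1, 1]")
    TRUE
})

#' PropFitResult: proportional-incorporation model fit
#'
#' Result of regressing the CL fatty-acid composition on the donor-pool
#' compositions under simplex constraints (weights nonnegative, summing
#' to 1).
#'
#' @slot weights named numeric donor-class weights on the simplex.
#' @slot clFA the CL chain distribution that was fit (typically the IID
#'   fit result).
#' @slot donorMatrix numeric matrix, chains x donor classes, aligned on the
#'   union chain support with zeros imputed.
#' @slot target numeric, the CL FA probabilities on the union support.
#' @slot fitted numeric, the weighted donor mixture.
#' @slot residuals numeric per-chain residuals (\code{target - fitted});
#'   positive means the chain is in excess in CL relative to proportional
#'   donation. They sum to 0.
#' @slot error sum of squared residuals.
#' @slot pearsonR Pearson correlation between target and fitted.
#' @slot nonUnique logical; \code{TRUE} when the donor vectors are affinely
#'   dependent so the optimal weights are not unique.
#' @exportClass PropFitResult
setClass("PropFitResult",
         representation(weights = "numeric",
                        clFA = "FADistribution",
                        donorMatrix = "matrix",
                        target = "numeric",
                        fitted = "numeric",
                        residuals = "numeric",
                        error = "numeric",
                        pearsonR = "numeric",
                        nonUnique = "logical"))

setValidity("PropFitResult", function(object) {
    w <- object@weights
    if (any(w < -1e-9) || abs(sum(w) - 1) > .TOL_NORM)
        return("weights must be nonnegative and sum to 1")
    if (abs(sum(object@residuals)) > 1e-6)
        return("residuals must sum to 0")
    TRUE
})

#' CVResult: repeated k-fold cross-validation of a positional model
#'
#' @slot r numeric vector of per-run merged-prediction Pearson correlations.
#' @slot model \code{"IID"} or \code{"IDD"}.
#' @slot folds integer number of folds.
#' @slot runs integer number of independent CV runs.
#' @slot seed integer seed used for the partitions.
#' @exportClass CVResult
setClass("CVResult",
         representation(r = "numeric",
                        model = "character",
                        folds = "integer",
                        runs = "integer",
                        seed = "integer"))

setValidity("CVResult", function(object) {
    if (object@runs < 1L) return("runs must be >= 1")
    if (length(object@r) != object@runs)
        return("one correlation per run is required")
    if (any(!is.na(object@r) & abs(object@r) > 1 + 1e-9))
        return("correlations must lie in [-1, 1]")
    TRUE
})

#' PermutationResult: permutation-null significance assessment
#'
#' @slot statistic character, name of the statistic.
#' @slot observed numeric observed statistic value(s).
#' @slot null numeric vector of null statistic values.
#' @slot pValue numeric p-value in (0, 1].
#' @slot method character description of how the p-value was obtained.
#' @exportClass PermutationResult
setClass("PermutationResult",
         representation(statistic = "character",
                        observed = "numeric",
                        null = "numeric",
                        pValue = "numeric",
                        method = "character"))

setValidity("PermutationResult", function(object) {
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue must lie in (0, 1]")
    TRUE
})

#' SyntheticTruth: ground truth for a generated benchmark dataset
#'
#' @slot pools named list of donor [FADistribution-class] pools.
#' @slot weights named numeric donor weights (simplex) or empty.
#' @slot clFA [FADistribution-class] CL chain distribution (IID truth), or
#'   the sn-1/sn-1' truth left \code{NULL} for pure proportional truths
#'   until derived.
#' @slot sn1,sn2 optional [FADistribution-class] for IDD truths (class
#'   \code{ANY}; \code{NULL} when unused).
#' @slot sigma numeric standard deviation of additive peak noise.
#' @slot seed integer seed.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(pools = "list",
                        weights = "numeric",
                        clFA = "ANY",
                        sn1 = "ANY",
                        sn2 = "ANY",
                        sigma = "numeric",
                        seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (length(object@weights) &&
        (any(object@weights < -1e-12) ||
         abs(sum(object@weights) - 1) > .TOL_NORM))
        return("weights must be nonnegative and sum to 1")
    TRUE
})
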