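## Accessor methods and show() methods for the package classes.

#' @rdname accessors
#' @aliases chainLabels,FADistribution-method
setMethod("chainLabels", "FADistribution", function(x)
    .cdLabel(x@carbons, x@doubleBonds))

#' @rdname accessors
#' @aliases probs,FADistribution-method
setMethod("probs", "FADistribution", function(x) {
    p <- x@probs
    names(p) <- chainLabels(x)
    p
})

#' @rdname accessors
#' @aliases peakLabels,CLProfile-method
setMethod("peakLabels", "CLProfile", function(x)
    .cdLabel(x@totalCarbons, x@totalDoubleBonds))

#' @rdname accessors
#' @aliases peakValues,CLProfile-method
setMethod("peakValues", "CLProfile", function(x) {
    v <- x@values
    names(v) <- peakLabels(x)
    v
})

#' @rdname accessors
#' @aliases fitError,CLFitResult-method
setMethod("fitError", "CLFitResult", function(x) x@error)

#' @rdname accessors
#' @aliases fitError,PropFitResult-method
setMethod("fitError", "PropFitResult", function(x) x@error)

#' @rdname accessors
#' @aliases pearsonR,CLFitResult-method
setMethod("pearsonR", "CLFitResult", function(x) x@pearsonR)

#' @rdname accessors
#' @aliases pearsonR,PropFitResult-method
setMethod("pearsonR", "PropFitResult", function(x) x@pearsonR)

#' @rdname accessors
#' @aliases faDistributions,CLFitResult-method
setMethod("faDistributions", "CLFitResult", function(x) x@fa)

#' @rdname accessors
#' @aliases cvCorrelations,CVResult-method
setMethod("cvCorrelations", "CVResult", function(x) x@r)

#' @rdname accessors
#' @aliases pValue,PermutationResult-method
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname accessors
#' @aliases donorPools,SampleDataset-method
setMethod("donorPools", "SampleDataset", function(x) x@donorPools)

#' @rdname accessors
#' @aliases clProfile,SampleDataset-method
setMethod("clProfile", "SampleDataset", function(x) x@clProfile)

#' @rdname accessors
#' @aliases sampleId,SampleDataset-method
setMethod("sampleId", "SampleDataset", function(x) x@sampleId)

#' Donor weights of a proportional-incorporation fit
#'
#' @param object a [PropFitResult-class].
#' @param ... ignored.
#' @return Named numeric vector of donor-class weights (simplex).
#' @aliases weights,PropFitResult-method
#' @export
setMethod("weights", "PropFitResult", function(object, ...) object@weights)

#' Per-chain residuals of a proportional-incorporation fit
#'
#' Positive residuals indicate an excess of the chain in CL over the
#' proportional-donation prediction.
#'
#' @param object a [PropFitResult-class].
#' @param ... ignored.
#' @return Named numeric vector of per-chain residuals, summing to 0.
#' @aliases residuals,PropFitResult-method
#' @export
setMethod("residuals", "PropFitResult", function(object, ...)
    object@residuals)

#' Fitted donor mixture of a proportional-incorporation fit
#'
#' @param object a [PropFitResult-class].
#' @param ... ignored.
#' @return Named numeric vector, the weighted donor mixture per chain.
#' @aliases fitted,PropFitResult-method
#' @export
setMethod("fitted", "PropFitResult", function(object, ...) object@fitted)

setMethod("show", "FADistribution", function(object) {
    cat(sprintf("FADistribution over %d chain type(s)\n",
                length(object@probs)))
    print(round(probs(object), 4))
    invisible(object)
})

setMethod("show", "CLProfile", function(object) {
    cat(sprintf("CLProfile (%s) over %d peak(s); total mass %.6f\n",
                object@kind, length(object@values), sum(object@values)))
    v <- peakValues(object)
    print(round(utils::head(v, 8), 4))
    if (length(v) > 8) cat(sprintf("... and %d more peak(s)\n",
                                   length(v) - 8L))
    invisible(object)
})

setMethod("show", "SampleDataset", function(object) {
    cat(sprintf("SampleDataset '%s': %d CL peak(s), donors {%s}, %d replicate(s)\n",
                object@sampleId, length(object@clProfile@values),
                paste(names(object@donorPools), collapse = ", "),
                object@nReplicates))
    invisible(object)
})

setMethod("show", "CLFitResult", function(object) {
    cat(sprintf("%s fit: error %.4g, Pearson r %.4f%s\n",
                object@model, object@error, object@pearsonR,
                if (length(object@unreachablePeaks))
                    sprintf(" (%d unreachable peak(s))",
                            length(object@unreachablePeaks)) else ""))
    cat(sprintf("  unassigned model mass: %.4g\n", object@unassignedMass))
    invisible(object)
})

setMethod("show", "PropFitResult", function(object) {
    cat("Proportional-incorporation fit\n  weights:\n")
    print(round(object@weights, 4))
    cat(sprintf("  error %.4g, Pearson r %.4f%s\n", object@error,
                object@pearsonR,
                if (object@nonUnique) " [non-unique weights]" else ""))
    invisible(object)
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("%d-fold cross-validation of the %s model (%d run(s)): r = %.2f +/- %.2f\n",
                object@folds, object@model, object@runs,
                mean(object@r), stats::sd(object@r)))
    invisible(object)
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("Permutation test of %s: observed %.4f, %d null value(s), p = %.4g\n",
                object@statistic, mean(object@observed),
                length(object@null), object@pValue))
    cat(sprintf("  method: %s\n", object@method))
    invisible(object)
})
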