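#' Accessor generics
#'
#' Small accessor family for the fit/result classes: \code{chainLabels}
#' returns ASCII \code{"C:D"} chain labels, \code{peakLabels} the
#' \code{"C:D"} peak labels, \code{probs} and \code{peakValues} the
#' numeric vectors, \code{fitError} the squared-error of a fit,
#' \code{pearsonR} its Pearson correlation, \code{faDistributions} the
#' fitted chain distribution(s), \code{cvCorrelations} the per-run
#' cross-validation correlations and \code{pValue} a permutation p-value.
#'
#' @param x an object of one of the package's S4 classes.
#' @return A vector (or list, for \code{faDistributions}) of the requested
#'   component.
#' @examples
#' fa <- FADistribution(c("18:1" = 0.5, "18:2" = 0.5))
#' chainLabels(fa)
#' probs(fa)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chainLabels", function(x) standardGeneric("chainLabels"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("peakLabels", function(x) standardGeneric("peakLabels"))

#' @rdname accessors
#' @export
setGeneric("peakValues", function(x) standardGeneric("peakValues"))

#' @rdname accessors
#' @export
setGeneric("fitError", function(x) standardGeneric("fitError"))

#' @rdname accessors
#' @export
setGeneric("pearsonR", function(x) standardGeneric("pearsonR"))

#' @rdname accessors
#' @export
setGeneric("faDistributions", function(x) standardGeneric("faDistributions"))

#' @rdname accessors
#' @export
setGeneric("cvCorrelations", function(x) standardGeneric("cvCorrelations"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("donorPools", function(x) standardGeneric("donorPools"))

#' @rdname accessors
#' @export
setGeneric("clProfile", function(x) standardGeneric("clProfile"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
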