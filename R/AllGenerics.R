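#' @include AllClasses.R
NULL

#' Accessors for calibration curves
#'
#' @param object a [CalibrationCurve-class].
#' @return a single numeric (or integer for `nStandards`, character vector for
#'   `flags`).
#' @name calibration-accessors
#' @aliases slope intercept rSquared blankSignal nStandards flags
#' @examples
#' cc <- fitCalibration(data.frame(amount = 0:2, signal = c(0, 0.5, 1)))
#' slope(cc)
#' rSquared(cc)
NULL

#' @rdname calibration-accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname calibration-accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname calibration-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname calibration-accessors
#' @export
setGeneric("blankSignal", function(object) standardGeneric("blankSignal"))

#' @rdname calibration-accessors
#' @export
setGeneric("nStandards", function(object) standardGeneric("nStandards"))

#' @rdname calibration-accessors
#' @export
setGeneric("flags", function(object) standardGeneric("flags"))

#' Accessors for Mito-Stress parameters
#'
#' @param object a [MitoParams-class].
#' @return a single numeric rate, in the units of the source trace.
#' @name mito-accessors
#' @aliases basalRespiration protonLeak atpLinkedRespiration
#'   maximalRespiration spareCapacity nonMitoRespiration couplingEfficiency
NULL

#' @rdname mito-accessors
#' @export
setGeneric("basalRespiration", function(object) standardGeneric("basalRespiration"))

#' @rdname mito-accessors
#' @export
setGeneric("protonLeak", function(object) standardGeneric("protonLeak"))

#' @rdname mito-accessors
#' @export
setGeneric("atpLinkedRespiration", function(object) standardGeneric("atpLinkedRespiration"))

#' @rdname mito-accessors
#' @export
setGeneric("maximalRespiration", function(object) standardGeneric("maximalRespiration"))

#' @rdname mito-accessors
#' @export
setGeneric("spareCapacity", function(object) standardGeneric("spareCapacity"))

#' @rdname mito-accessors
#' @export
setGeneric("nonMitoRespiration", function(object) standardGeneric("nonMitoRespiration"))

#' @rdname mito-accessors
#' @export
setGeneric("couplingEfficiency", function(object) standardGeneric("couplingEfficiency"))

#' ATP formed per molecule of oxygen consumed
#'
#' Derived from the glutamine stoichiometry: `atpPerGlutamine / o2PerGlutamine`
#' (5 with the default constants, consistent with 30 ATP per 6 O2 for glucose).
#'
#' @param object a [StoichiometryConstants-class].
#' @return a single positive numeric.
#' @export
setGeneric("atpPerO2", function(object) standardGeneric("atpPerO2"))

#' Accessors for Venn partitions
#'
#' @param object a [VennPartition-class].
#' @return `vennRegions`: a named list of seven disjoint gene-id vectors;
#'   `vennCounts`: a named numeric of region sizes; `vennTotals`: per-set
#'   totals.
#' @name venn-accessors
#' @aliases vennRegions vennCounts vennTotals
NULL

#' @rdname venn-accessors
#' @export
setGeneric("vennRegions", function(object) standardGeneric("vennRegions"))

#' @rdname venn-accessors
#' @export
setGeneric("vennCounts", function(object) standardGeneric("vennCounts"))

#' @rdname venn-accessors
#' @export
setGeneric("vennTotals", function(object) standardGeneric("vennTotals"))

#' Accessors for concordance results
#'
#' @param object a [ConcordanceResult-class].
#' @return a single numeric.
#' @name concordance-accessors
#' @aliases fractionSameSign concordanceSlope
NULL

#' @rdname concordance-accessors
#' @export
setGeneric("fractionSameSign", function(object) standardGeneric("fractionSameSign"))

#' @rdname concordance-accessors
#' @export
setGeneric("concordanceSlope", function(object) standardGeneric("concordanceSlope"))

#' Condition labels of a design or truth object
#'
#' @param object an [ExperimentDesign-class].
#' @return character vector of condition labels, in design order.
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
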