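## Generics, accessors and show methods.

#' @rdname SpikeTrainSet-class
#' @param object,x an object.
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("trialDuration", function(x) standardGeneric("trialDuration"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname SpikeTrainSet-class
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname BinnedCounts-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedCounts-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @describeIn SpikeTrainSet-class unit roster.
#' @export
setMethod("unitIds", "SpikeTrainSet", function(x) x@unitIds)

#' @describeIn SpikeTrainSet-class named list of spike-time vectors.
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x) x@spikeTimes)

#' @describeIn SpikeTrainSet-class trial duration in seconds.
#' @export
setMethod("trialDuration", "SpikeTrainSet", function(x) x@duration)

#' @describeIn SpikeTrainSet-class condition label.
#' @export
setMethod("conditionLabel", "SpikeTrainSet", function(x) x@condition)

#' @describeIn SpikeTrainSet-class number of units.
#' @export
setMethod("nUnits", "SpikeTrainSet", function(x) length(x@unitIds))

setMethod("show", "SpikeTrainSet", function(object) {
  ns <- vapply(object@spikeTimes, length, integer(1))
  cat(sprintf(
    "SpikeTrainSet: %d units, %.1f s, condition %s (session %s)\n",
    length(object@unitIds), object@duration, object@condition,
    object@sessionId))
  cat(sprintf("  spikes: total %d, per-unit median %.0f (range %d-%d)\n",
              sum(ns), stats::median(ns), min(ns), max(ns)))
})

#' @describeIn BinnedCounts-class bin-by-unit count matrix.
#' @param object a \linkS4class{BinnedCounts} object.
#' @export
setMethod("counts", "BinnedCounts", function(object) object@counts)

#' @describeIn BinnedCounts-class bin width in seconds.
#' @param x a \linkS4class{BinnedCounts} object.
#' @export
setMethod("binWidth", "BinnedCounts", function(x) x@binWidth)

#' @describeIn BinnedCounts-class number of bins.
#' @export
setMethod("nBins", "BinnedCounts", function(x) nrow(x@counts))

#' @describeIn BinnedCounts-class unit roster (column names).
#' @export
setMethod("unitIds", "BinnedCounts", function(x) colnames(x@counts))

#' @describeIn BinnedCounts-class condition label.
#' @export
setMethod("conditionLabel", "BinnedCounts", function(x) x@condition)

#' @describeIn BinnedCounts-class number of units.
#' @export
setMethod("nUnits", "BinnedCounts", function(x) ncol(x@counts))

setMethod("show", "BinnedCounts", function(object) {
  cat(sprintf(
    "BinnedCounts: %d bins x %d units at %.4g s (condition %s)\n",
    nrow(object@counts), ncol(object@counts), object@binWidth,
    object@condition))
  cat(sprintf("  total spikes %d, mean count per bin %.4g\n",
              sum(object@counts), mean(object@counts)))
})

setMethod("show", "SimNetworkSpec", function(object) {
  cat(sprintf(
    "SimNetworkSpec: J = %d, %.0f s at %.4g s bins, %d links, seed %d\n",
    object@J, object@duration, object@binWidth,
    sum(object@beta != 0), object@seed))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf(
    "ModelSpec: type %s, response bin %.4g s, history window %.4g s%s\n",
    object@modelType, object@responseBin, object@historyWindow,
    if (object@includeSelf) " (self-history)" else ""))
})

setMethod("show", "NeuronFit", function(object) {
  cat(sprintf(
    "NeuronFit (type %s) target %s: %d coefficients, loglik %.2f\n",
    object@modelType, object@target, length(object@coef), object@loglik))
  cat(sprintf("  converged: %s, degenerate: %s, spikes %d / %d bins\n",
              object@converged, object@degenerate, object@spikeCount,
              object@nObs))
})

setMethod("show", "GOFResult", function(object) {
  if (object@assessable)
    cat(sprintf(
      "GOFResult %s: KS %.4f vs band %.4f over %d intervals -> %s\n",
      object@target, object@ksStat, object@band, object@nIntervals,
      if (object@wellFit) "well fitted" else "rejected"))
  else
    cat(sprintf("GOFResult %s: not assessable (%d intervals)\n",
                object@target, object@nIntervals))
})

setMethod("show", "ConnectivityMap", function(object) {
  cat(sprintf(
    "ConnectivityMap (%s, type %s at %.4g s): %d significant links over %d units\n",
    object@condition, object@modelSpec@modelType,
    object@modelSpec@responseBin, sum(object@beta != 0), nrow(object@beta)))
})

setMethod("show", "BinaryMap", function(object) {
  cat(sprintf("BinaryMap (%s): %d links over %d units\n",
              object@condition, sum(object@links), nrow(object@links)))
})

setMethod("show", "MechanicsSpec", function(object) {
  cat(sprintf(
    "MechanicsSpec: kE %.3g N/m (plane %.3g m below rest), kN %.3g N/m, xN0 %.3g m, window %.3g s\n",
    object@kE, object@xE0Offset, object@kN, object@xN0, object@rateWindow))
})
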