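## S4 class definitions and validity methods.

#' SpikeTrainSet: per-unit spike times for one trial/condition
#'
#' Holds sorted spike times (seconds) for every unit recorded in one trial,
#' together with the trial duration and its condition label. Units with no
#' spikes are retained so the unit roster stays stable across the three
#' conditions of a session.
#'
#' @slot unitIds character vector of unit identifiers.
#' @slot spikeTimes named list, one sorted numeric vector of spike times
#'   (seconds) per unit.
#' @slot duration trial duration in seconds.
#' @slot condition condition label, typically \code{"BL"}, \code{"E"} or
#'   \code{"BMI/E"}.
#' @slot sessionId session identifier.
#' @exportClass SpikeTrainSet
setClass("SpikeTrainSet",
  representation(
    unitIds = "character",
    spikeTimes = "list",
    duration = "numeric",
    condition = "character",
    sessionId = "character"
  )
)

setValidity("SpikeTrainSet", function(object) {
  msg <- character()
  if (length(object@unitIds) < 1L)
    msg <- c(msg, "at least one unit is required")
  if (length(object@spikeTimes) != length(object@unitIds))
    msg <- c(msg, "spikeTimes must have one entry per unit")
  if (!identical(names(object@spikeTimes), object@unitIds))
    msg <- c(msg, "names(spikeTimes) must equal unitIds")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  for (u in object@unitIds) {
    tt <- object@spikeTimes[[u]]
    if (length(tt) == 0L) next
    if (!is.numeric(tt) || anyNA(tt) || any(!is.finite(tt)))
      msg <- c(msg, sprintf("unit %s: spike times must be finite numbers", u))
    else {
      if (any(tt < 0) || any(tt > object@duration))
        msg <- c(msg, sprintf("unit %s: spike times outside [0, duration]", u))
      if (length(tt) > 1L && any(diff(tt) <= 0))
        msg <- c(msg, sprintf("unit %s: spike times must be strictly increasing", u))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinnedCounts: bin-by-unit spike count matrix
#'
#' Spike counts on a regular time grid. Bin \code{k} covers the half-open
#' interval \code{[t0 + (k-1)*binWidth, t0 + k*binWidth)}, so every spike
#' lands in exactly one bin and the per-unit column sums equal the spike
#' counts of the source \linkS4class{SpikeTrainSet} (count conservation).
#'
#' @slot counts integer matrix, K bins (rows) by J units (columns), with
#'   column names the unit roster.
#' @slot binWidth bin width in seconds.
#' @slot t0 start time of the first bin (seconds).
#' @slot condition condition label carried over from the spike trains.
#' @exportClass BinnedCounts
setClass("BinnedCounts",
  representation(
    counts = "matrix",
    binWidth = "numeric",
    t0 = "numeric",
    condition = "character"
  )
)

setValidity("BinnedCounts", function(object) {
  msg <- character()
  cc <- object@counts
  if (!is.numeric(cc)) msg <- c(msg, "counts must be numeric")
  else {
    if (anyNA(cc) || any(cc < 0)) msg <- c(msg, "counts must be >= 0")
    if (any(cc != round(cc))) msg <- c(msg, "counts must be integers")
  }
  if (is.null(colnames(cc))) msg <- c(msg, "counts must have unit column names")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' SimNetworkSpec: ground-truth generative spike network
#'
#' Specification of a coupled-GLM (conditional-intensity) network used by
#' \code{\link{simulateGLMNetwork}}. Neuron \code{i} fires in bin \code{k}
#' with probability \code{min(exp(mu[i] + sum_j beta[i, j] * c_j(k-1)), 1)},
#' where \code{c_j(k-1)} is neuron \code{j}'s count in the preceding bin.
#' Rows of \code{beta} are targets, columns are sources.
#'
#' @slot J number of neurons.
#' @slot mu per-neuron baseline log rate (log spikes per bin);
#'   \code{exp(mu)} must not exceed 1.
#' @slot beta J x J coupling matrix (log-rate increment per source spike in
#'   the preceding bin); zero diagonal unless self-history is enabled.
#' @slot binWidth simulation bin width in seconds.
#' @slot duration simulated duration in seconds.
#' @slot selfHistory logical; allow nonzero diagonal couplings.
#' @slot seed integer seed making the simulation reproducible.
#' @exportClass SimNetworkSpec
setClass("SimNetworkSpec",
  representation(
    J = "integer",
    mu = "numeric",
    beta = "matrix",
    binWidth = "numeric",
    duration = "numeric",
    selfHistory = "logical",
    seed = "integer"
  )
)

setValidity("SimNetworkSpec", function(object) {
  msg <- character()
  J <- object@J
  if (length(J) != 1L || J < 1L) msg <- c(msg, "J must be a positive integer")
  if (length(object@mu) != J) msg <- c(msg, "mu must have length J")
  if (any(!is.finite(object@mu)))
    msg <- c(msg, "mu must be finite (a zero-rate neuron is not representable)")
  if (any(exp(object@mu) > 1 + 1e-12))
    msg <- c(msg, "exp(mu) must be <= 1 per bin (baseline sub-saturation)")
  if (!all(dim(object@beta) == c(J, J))) msg <- c(msg, "beta must be J x J")
  if (any(!is.finite(object@beta))) msg <- c(msg, "beta must be finite")
  if (!isTRUE(object@selfHistory) && any(diag(object@beta) != 0))
    msg <- c(msg, "beta diagonal must be zero when selfHistory is FALSE")
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be positive")
  if (length(object@duration) != 1L || object@duration < object@binWidth)
    msg <- c(msg, "duration must be at least one bin")
  if (length(msg)) msg else TRUE
})

#' ConditionSeriesSpec: condition series with designed connection overlap
#'
#' Describes a series of generative networks (one per task condition) that
#' share a controlled fraction of their nonzero couplings, emulating a
#' persistent core of functional connections across conditions.
#'
#' With a scalar \code{overlapFraction}, consecutive conditions share
#' exactly \code{round(overlapFraction * connectionCount)} links (identical
#' position and value). With a length-3 \code{overlapFraction} and
#' \code{nConditions = 3}, the three pairwise overlaps (1-2, 2-3, 1-3) are
#' planted exactly, via disjoint shared-link sets.
#'
#' @slot base \linkS4class{SimNetworkSpec} providing \code{J}, \code{mu},
#'   bin width and duration; its \code{beta} is ignored.
#' @slot nConditions number of conditions in the series.
#' @slot overlapFraction fraction(s) in [0, 1] of links shared (see above).
#' @slot positiveFraction fraction of links with positive sign.
#' @slot connectionCount nonzero links per condition.
#' @slot betaRange range of |beta| for planted links.
#' @slot seed integer seed.
#' @exportClass ConditionSeriesSpec
setClass("ConditionSeriesSpec",
  representation(
    base = "SimNetworkSpec",
    nConditions = "integer",
    overlapFraction = "numeric",
    positiveFraction = "numeric",
    connectionCount = "integer",
    betaRange = "numeric",
    seed = "integer"
  )
)

setValidity("ConditionSeriesSpec", function(object) {
  msg <- character()
  J <- object@base@J
  if (object@nConditions < 2L) msg <- c(msg, "nConditions must be >= 2")
  ov <- object@overlapFraction
  if (!length(ov) %in% c(1L, 3L))
    msg <- c(msg, "overlapFraction must have length 1 (chain) or 3 (pairwise)")
  if (length(ov) == 3L && object@nConditions != 3L)
    msg <- c(msg, "pairwise overlapFraction requires nConditions = 3")
  if (any(ov < 0 | ov > 1)) msg <- c(msg, "overlapFraction must be in [0, 1]")
  pf <- object@positiveFraction
  if (length(pf) != 1L || pf < 0 || pf > 1)
    msg <- c(msg, "positiveFraction must be in [0, 1]")
  if (object@connectionCount < 1L ||
      object@connectionCount > J * (J - 1L))
    msg <- c(msg, "connectionCount must be in [1, J*(J-1)]")
  if (length(object@betaRange) != 2L || any(object@betaRange <= 0) ||
      diff(object@betaRange) < 0)
    msg <- c(msg, "betaRange must be an increasing pair of positive magnitudes")
  if (length(msg)) msg else TRUE
})

#' MechanicsSpec: elastic-load and neural-driven force-field parameters
#'
#' Parameters of the robot-applied vertical force fields of the locomotor
#' BMI paradigm. Heights are measured upward from the horizontal
#' equilibrium plane of the elastic load field, which sits
#' \code{xE0Offset} below the animal's normal pelvic height.
#'
#' @slot kE elastic-load field stiffness (N/m), default 44.
#' @slot xE0Offset depth of the equilibrium plane below normal pelvic
#'   height (m), default 0.0125.
#' @slot kN neural-field stiffness (N/m), default 80.
#' @slot xN0 neural-field equilibrium point above the plane (m),
#'   default 0.055.
#' @slot rateWindow aggregate-rate window (seconds), default 0.1.
#' @slot rateNorm population spike count in one window that normalizes the
#'   aggregate rate to 1.0.
#' @slot treadmillSpeed treadmill speed (m/s), metadata only.
#' @slot bodyStiffness restoring stiffness of the simulated pelvis toward
#'   normal height (N/m).
#' @slot damping viscous damping of the simulated pelvis (N s/m).
#' @exportClass MechanicsSpec
setClass("MechanicsSpec",
  representation(
    kE = "numeric",
    xE0Offset = "numeric",
    kN = "numeric",
    xN0 = "numeric",
    rateWindow = "numeric",
    rateNorm = "numeric",
    treadmillSpeed = "numeric",
    bodyStiffness = "numeric",
    damping = "numeric"
  )
)

setValidity("MechanicsSpec", function(object) {
  msg <- character()
  for (s in c("kE", "kN", "bodyStiffness", "damping"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("%s must be >= 0", s))
  if (object@rateWindow <= 0) msg <- c(msg, "rateWindow must be > 0")
  if (object@rateNorm <= 0) msg <- c(msg, "rateNorm must be > 0")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: point-process GLM model specification
#'
#' Defines the response binning and history window of a type I
#' (homogeneous Poisson) or type II (neighbor-history) model. The
#' canonical timescales are 1 ms and 10 ms with a one-step history window
#' (\code{historyWindow == responseBin}), so both timescale models carry
#' one coefficient per source neuron. A longer \code{historyWindow} sums
#' source counts over \code{historyWindow / responseBin} preceding bins.
#'
#' @slot responseBin response bin width Delta in seconds (canonically
#'   0.001 or 0.010).
#' @slot historyWindow history window W in seconds; must be an integer
#'   multiple of \code{responseBin}. Covariates are source spike counts in
#'   the W-window strictly preceding each response bin.
#' @slot includeSelf logical; include the target's own history (type B).
#' @slot modelType \code{"I"} or \code{"II"}.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    responseBin = "numeric",
    historyWindow = "numeric",
    includeSelf = "logical",
    modelType = "character"
  )
)

setValidity("ModelSpec", function(object) {
  if (!length(object@responseBin)) return(TRUE)  # uninitialized prototype
  msg <- character()
  if (object@responseBin <= 0) msg <- c(msg, "responseBin must be > 0")
  L <- object@historyWindow / object@responseBin
  if (object@historyWindow <= 0 || abs(L - round(L)) > 1e-8)
    msg <- c(msg,
      "historyWindow must be a positive integer multiple of responseBin")
  if (!object@modelType %in% c("I", "II"))
    msg <- c(msg, "modelType must be 'I' or 'II'")
  if (length(msg)) msg else TRUE
})

#' NeuronFit: fitted point-process GLM for one target neuron
#'
#' Maximum-likelihood fit of a per-neuron conditional-intensity model:
#' either type I (intercept only, closed form) or type II (intercept plus
#' one history coefficient per source unit). Uncertainty is Wald, from the
#' inverse observed information at the optimum.
#'
#' @slot target target unit id.
#' @slot modelType \code{"I"} or \code{"II"}.
#' @slot coef named coefficient vector; \code{"(Intercept)"} is the
#'   baseline log count per bin, remaining names are source unit ids.
#' @slot se standard errors (same order as \code{coef}).
#' @slot cov coefficient covariance matrix.
#' @slot loglik maximized Poisson log-likelihood.
#' @slot nullLoglik log-likelihood of the intercept-only model on the same
#'   response rows (nested-model reference).
#' @slot converged logical convergence flag.
#' @slot degenerate logical; TRUE when the fit is unusable (e.g. zero
#'   spikes, or a diverging coefficient indicating separation).
#' @slot pValues two-sided Wald p-values per coefficient.
#' @slot ci95 two-column matrix of 95\% Wald confidence limits.
#' @slot nObs number of response bins used.
#' @slot spikeCount target spike count over the used bins.
#' @slot sources source unit ids (column order of the design).
#' @slot modelSpec the \linkS4class{ModelSpec} the design was built with.
#' @exportClass NeuronFit
setClass("NeuronFit",
  representation(
    target = "character",
    modelType = "character",
    modelSpec = "ModelSpec",
    coef = "numeric",
    se = "numeric",
    cov = "matrix",
    loglik = "numeric",
    nullLoglik = "numeric",
    converged = "logical",
    degenerate = "logical",
    pValues = "numeric",
    ci95 = "matrix",
    nObs = "integer",
    spikeCount = "integer",
    sources = "character"
  )
)

setValidity("NeuronFit", function(object) {
  msg <- character()
  p <- length(object@coef)
  if (length(object@se) != p) msg <- c(msg, "se length must match coef")
  if (p > 0 && !all(dim(object@cov) == c(p, p)))
    msg <- c(msg, "cov must be p x p")
  if (p > 0 && !isTRUE(all.equal(object@cov, t(object@cov),
                                 tolerance = 1e-6, check.attributes = FALSE)))
    msg <- c(msg, "cov must be symmetric")
  if (length(object@pValues) != p) msg <- c(msg, "pValues length must match coef")
  if (p > 0 && !all(dim(object@ci95) == c(p, 2L)))
    msg <- c(msg, "ci95 must be p x 2")
  if (length(msg)) msg else TRUE
})

#' GOFResult: time-rescaling goodness of fit for one unit
#'
#' @slot target unit id.
#' @slot tau rescaled inter-spike intervals (unit-rate exponential scale).
#' @slot z uniform-transformed intervals, \code{1 - exp(-tau)}.
#' @slot ksStat Kolmogorov-Smirnov sup distance of sorted \code{z} to the
#'   mid-grid uniform quantiles.
#' @slot band critical KS distance at the chosen level.
#' @slot wellFit logical; \code{ksStat < band}.
#' @slot nIntervals number of intervals entering the test.
#' @slot assessable logical; FALSE when too few intervals are available.
#' @exportClass GOFResult
setClass("GOFResult",
  representation(
    target = "character",
    tau = "numeric",
    z = "numeric",
    ksStat = "numeric",
    band = "numeric",
    wellFit = "logical",
    nIntervals = "integer",
    assessable = "logical"
  )
)

setValidity("GOFResult", function(object) {
  msg <- character()
  if (length(object@z) && (any(object@z < 0) || any(object@z > 1)))
    msg <- c(msg, "z must lie in [0, 1]")
  if (isTRUE(object@assessable) &&
      !identical(object@wellFit, unname(object@ksStat < object@band)))
    msg <- c(msg, "wellFit must equal ksStat < band")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMap: signed functional-connectivity matrix
#'
#' J x J matrix of significant history coefficients, with entry
#' \code{(i, j)} the fitted coefficient of source \code{j} on target
#' \code{i}; entries of non-significant coefficients, and all rows of
#' targets without a converged well-fitted model, are zero.
#'
#' @slot beta J x J signed coefficient matrix (rows = targets,
#'   columns = sources), dimnames = unit roster.
#' @slot fittedMask named logical vector: which targets contributed a
#'   converged, well-fitted model.
#' @slot condition condition label.
#' @slot modelSpec the \linkS4class{ModelSpec} used.
#' @slot alpha significance level of the coefficient mask.
#' @exportClass ConnectivityMap
setClass("ConnectivityMap",
  representation(
    beta = "matrix",
    fittedMask = "logical",
    condition = "character",
    modelSpec = "ModelSpec",
    alpha = "numeric"
  )
)

setValidity("ConnectivityMap", function(object) {
  msg <- character()
  b <- object@beta
  if (nrow(b) != ncol(b)) msg <- c(msg, "beta must be square")
  if (is.null(rownames(b)) || !identical(rownames(b), colnames(b)))
    msg <- c(msg, "beta must carry identical row and column unit names")
  if (length(object@fittedMask) != nrow(b))
    msg <- c(msg, "fittedMask must have one entry per target")
  if (!isTRUE(object@modelSpec@includeSelf) && any(diag(b) != 0))
    msg <- c(msg, "diagonal must be zero without self-history")
  if (any(b[!object@fittedMask, , drop = FALSE] != 0))
    msg <- c(msg, "rows of unfitted targets must be zero")
  if (length(msg)) msg else TRUE
})

#' BinaryMap: thresholded 0/1 connectivity matrix
#'
#' Indicator twin of a \linkS4class{ConnectivityMap}: entries are 1 where
#' the signed map is nonzero (a significant link), 0 elsewhere.
#'
#' @slot links 0/1 matrix, same shape and orientation as the signed map.
#' @slot condition condition label.
#' @slot includeSelf logical; whether self-links are possible.
#' @exportClass BinaryMap
setClass("BinaryMap",
  representation(
    links = "matrix",
    condition = "character",
    includeSelf = "logical"
  )
)

setValidity("BinaryMap", function(object) {
  msg <- character()
  l <- object@links
  if (nrow(l) != ncol(l)) msg <- c(msg, "links must be square")
  if (!all(l %in% c(0, 1))) msg <- c(msg, "links must be 0/1")
  if (!isTRUE(object@includeSelf) && any(diag(l) != 0))
    msg <- c(msg, "diagonal must be zero without self-history")
  if (length(msg)) msg else TRUE
})
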