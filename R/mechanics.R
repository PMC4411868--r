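## Elastic-load / neural-driven force laws and the closed-loop session
## simulator.

#' Construct a MechanicsSpec
#'
#' Defaults reproduce the force-field parameters of the emulated
#' locomotor BMI paradigm: a 44 N/m elastic load whose equilibrium plane
#' sits 12.5 mm below normal pelvic height (about 15\% body weight at
#' rest), and a neural-driven field with stiffness 80 N/m, equilibrium
#' point 55 mm, driven by the aggregate population rate of the preceding
#' 100 ms.
#'
#' @param kE elastic-load stiffness (N/m).
#' @param xE0Offset equilibrium-plane depth below normal pelvic height (m).
#' @param kN neural-field stiffness (N/m).
#' @param xN0 neural-field equilibrium point (m above the plane).
#' @param rateWindow aggregate-rate window (s).
#' @param rateNorm population spike count per window that maps to an
#'   aggregate rate of 1.0 (explicit normalization; the drive is
#'   unitless). Default 30, i.e. a 20-unit ensemble at 15 Hz.
#' @param treadmillSpeed treadmill speed (m/s), metadata.
#' @param bodyStiffness restoring stiffness of the simulated pelvis toward
#'   normal height (N/m); plant model, not a measured quantity.
#' @param damping viscous damping of the simulated pelvis (N s/m).
#' @return a \linkS4class{MechanicsSpec}.
#' @export
MechanicsSpec <- function(kE = 44, xE0Offset = 0.0125, kN = 80,
                          xN0 = 0.055, rateWindow = 0.1, rateNorm = 30,
                          treadmillSpeed = 0.125, bodyStiffness = 200,
                          damping = 10) {
  new("MechanicsSpec", kE = kE, xE0Offset = xE0Offset, kN = kN, xN0 = xN0,
      rateWindow = rateWindow, rateNorm = rateNorm,
      treadmillSpeed = treadmillSpeed, bodyStiffness = bodyStiffness,
      damping = damping)
}

#' Elastic-load force
#'
#' Vertical force of the elastic load field at pelvis height \code{X},
#' measured upward from the field's horizontal equilibrium plane:
#' \code{F_e = -kE * X}. Above the plane (\code{X > 0}, the normal walking
#' posture) the force is downward loading; it vanishes on the plane. The
#' restoring form is kept on both sides of the plane. Positive return
#' values point upward.
#'
#' @param X pelvis height above the equilibrium plane (m); vectorized.
#' @param mech a \linkS4class{MechanicsSpec}.
#' @return force in newtons (positive = upward).
#' @examples
#' elasticForce(0.0125, MechanicsSpec())  # -0.55 N at normal height
#' @export
elasticForce <- function(X, mech = MechanicsSpec()) {
  stopifnot(is(mech, "MechanicsSpec"))
  -mech@kE * X
}

#' Neural-driven lifting force
#'
#' Force of the neural-driven elastic field,
#' \code{F_n = kN * N_af * (X - xN0)} in the field's native convention.
#' Because the equilibrium point \code{xN0} lies above the pelvis,
#' \code{X < xN0} and the field lifts; the value returned here uses the
#' upward-positive convention, i.e. \code{kN * N_af * (xN0 - X)}, so a
#' positive result is a lifting force. Set \code{convention = "raw"} for
#' the unflipped product.
#'
#' @param Naf aggregate (normalized) population firing rate, >= 0.
#' @param X pelvis height above the equilibrium plane (m).
#' @param mech a \linkS4class{MechanicsSpec}.
#' @param convention \code{"upward"} (default) or \code{"raw"}.
#' @return force in newtons.
#' @examples
#' neuralForce(0.1, 0.0125, MechanicsSpec())  # 0.34 N lift
#' @export
neuralForce <- function(Naf, X, mech = MechanicsSpec(),
                        convention = c("upward", "raw")) {
  stopifnot(is(mech, "MechanicsSpec"), all(Naf >= 0))
  convention <- match.arg(convention)
  raw <- mech@kN * Naf * (X - mech@xN0)
  if (convention == "raw") raw else -raw
}

#' Aggregate population firing rate
#'
#' Population spike count in the window \code{(t - rateWindow, t]},
#' divided by \code{rateNorm}. This is the (unitless) neural drive
#' \code{N_af} of the BMI force law.
#'
#' @param counts a \linkS4class{BinnedCounts}.
#' @param t evaluation time (s); must be at least one window after the
#'   start of the counts.
#' @param mech a \linkS4class{MechanicsSpec}.
#' @return normalized aggregate rate (scalar).
#' @export
aggregateRate <- function(counts, t, mech = MechanicsSpec()) {
  stopifnot(is(counts, "BinnedCounts"))
  if (t < counts@t0 + mech@rateWindow)
    stop("t must be at least rateWindow after the start of the counts")
  dt <- counts@binWidth
  K <- nrow(counts@counts)
  kHi <- min(K, as.integer(floor(round((t - counts@t0) / dt, 9) + 1e-9)))
  kLo <- max(0L, as.integer(ceiling(round((t - mech@rateWindow - counts@t0) / dt, 9) - 1e-9)))
  if (kHi <= kLo) return(0)
  sum(counts@counts[(kLo + 1L):kHi, , drop = FALSE]) / mech@rateNorm
}

#' Simulate a three-condition BMI session
#'
#' Generates the spike trains and mechanical traces of one session of the
#' emulated paradigm: a baseline trial (BL, no load), an elastic-load
#' trial (E) and a BMI-with-load trial (BMI/E), each from its own
#' ground-truth network of a \linkS4class{ConditionSeriesSpec} (so the
#' conditions share a designed core of connections). The load conditions
#' add a small constant offset to the baseline log rates
#' (\code{loadOffset}); firing-rate distributions in this paradigm change
#' little across conditions, so the default is modest.
#'
#' Pelvis height (relative to the load field's equilibrium plane) follows
#' an overdamped first-order plant,
#' \code{damping * dX/dt = bodyStiffness * (Xrest - X) + F_e + F_n},
#' integrated at the spike bin width. In E the neural field is off; in
#' BMI/E \code{F_n} is driven by the simulated population's aggregate rate
#' over the preceding \code{rateWindow}. With \code{kN = 0} the BMI/E
#' trace reduces to the E trace. Everything is reproducible from the
#' series seed.
#'
#' @param series a \linkS4class{ConditionSeriesSpec} with 3 conditions.
#' @param mech a \linkS4class{MechanicsSpec}.
#' @param loadOffset additive log-rate offset for the two load conditions.
#' @return list with \code{trains} (named list of three
#'   \linkS4class{SpikeTrainSet}s), \code{counts} (matching
#'   \linkS4class{BinnedCounts}), \code{traces} (per condition, a
#'   data.frame of time, X, Fe, Fn, Naf), \code{specs} (the ground-truth
#'   network per condition) and \code{groundTruth} (beta support lists).
#' @export
simulateBMISession <- function(series, mech = MechanicsSpec(),
                               loadOffset = 0.05) {
  stopifnot(is(series, "ConditionSeriesSpec"))
  if (series@nConditions != 3L)
    stop("a BMI session has exactly three conditions (BL, E, BMI/E)")
  specs <- makeConditionSeries(series)
  conds <- c("BL", "E", "BMI/E")
  names(specs) <- conds
  ## load conditions: constant additive offset on mu (clamped to keep
  ## exp(mu) <= 1)
  for (cond in c("E", "BMI/E"))
    specs[[cond]]@mu <- pmin(specs[[cond]]@mu + loadOffset, 0)
  sims <- lapply(conds, function(cond)
    simulateGLMNetwork(specs[[cond]], condition = cond))
  names(sims) <- conds
  traces <- list(
    BL = traceCondition(sims$BL$counts, mech, load = FALSE, bmi = FALSE),
    E = traceCondition(sims$E$counts, mech, load = TRUE, bmi = FALSE),
    `BMI/E` = traceCondition(sims$`BMI/E`$counts, mech, load = TRUE,
                             bmi = TRUE)
  )
  list(
    trains = lapply(sims, `[[`, "trains"),
    counts = lapply(sims, `[[`, "counts"),
    traces = traces,
    specs = specs,
    groundTruth = lapply(specs, function(s) {
      idx <- which(s@beta != 0, arr.ind = TRUE)
      data.frame(target = idx[, 1], source = idx[, 2],
                 beta = s@beta[idx])
    })
  )
}

## Integrate the pelvis plant for one condition.
traceCondition <- function(counts, mech, load, bmi) {
  dt <- counts@binWidth
  K <- nrow(counts@counts)
  Xrest <- mech@xE0Offset           # normal pelvic height above the plane
  X <- numeric(K)
  Fe <- numeric(K)
  Fn <- numeric(K)
  Naf <- numeric(K)
  X[1] <- Xrest
  winBins <- max(1L, as.integer(round(mech@rateWindow / dt)))
  pop <- rowSums(counts@counts)
  cpop <- c(0, cumsum(pop))
  for (k in seq_len(K - 1L)) {
    Fe[k] <- if (load) elasticForce(X[k], mech) else 0
    if (bmi && k > winBins) {
      Naf[k] <- (cpop[k + 1L] - cpop[k + 1L - winBins]) / mech@rateNorm
      Fn[k] <- neuralForce(Naf[k], X[k], mech)
    }
    dX <- (mech@bodyStiffness * (Xrest - X[k]) + Fe[k] + Fn[k]) /
      mech@damping
    X[k + 1L] <- X[k] + dt * dX
    if (!is.finite(X[k + 1L]) || abs(X[k + 1L]) > 0.5)
      stop("pelvis height diverged; use a smaller neural-field gain (kN) ",
           "or stronger damping")
  }
  Fe[K] <- if (load) elasticForce(X[K], mech) else 0
  data.frame(time = (seq_len(K) - 1) * dt, X = X, Fe = Fe, Fn = Fn,
             Naf = Naf)
}
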