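## Ground-truth coupled-GLM network simulation.

#' Construct a SimNetworkSpec
#'
#' @param J neuron count.
#' @param mu per-neuron baseline log rate (log spikes per bin); recycled to
#'   length \code{J}. \code{exp(mu)} must be at most 1.
#' @param beta J x J coupling matrix; default all zero.
#' @param binWidth bin width in seconds (default 1 ms).
#' @param duration simulated duration in seconds (default 120 s, the trial
#'   length of the emulated paradigm).
#' @param selfHistory allow nonzero diagonal couplings (type B networks).
#' @param seed integer seed.
#' @return a \linkS4class{SimNetworkSpec}.
#' @export
SimNetworkSpec <- function(J, mu, beta = NULL, binWidth = 0.001,
                           duration = 120, selfHistory = FALSE, seed = 1L) {
  J <- as.integer(J)
  mu <- rep_len(as.numeric(mu), J)
  if (is.null(beta)) beta <- matrix(0, J, J)
  new("SimNetworkSpec", J = J, mu = mu, beta = beta,
      binWidth = as.numeric(binWidth), duration = as.numeric(duration),
      selfHistory = isTRUE(selfHistory), seed = as.integer(seed))
}

#' Simulate a coupled-GLM spike network
#'
#' Generates binary per-bin spike counts from the generative twin of the
#' neighbor-history model: in bin \code{k >= 2}, neuron \code{i} fires
#' with probability
#' \code{p_i(k) = min(exp(mu_i + sum_j beta_ij c_j(k-1)), 1)}, a Bernoulli
#' emission; the first bin uses the baseline alone. At millisecond bins
#' the Bernoulli/Poisson distinction is negligible and probabilities stay
#' valid by construction. If clipping at 1 affects more than 0.1\% of bins
#' the affected (runaway) neurons are reported in a warning.
#'
#' The same spec and seed give bit-identical output.
#'
#' @param spec a \linkS4class{SimNetworkSpec}.
#' @param returnTrains also build the \linkS4class{SpikeTrainSet} (spike
#'   times at bin centers); set \code{FALSE} to save time in simulation
#'   studies that only need counts.
#' @param condition condition label attached to the outputs.
#' @return list with elements \code{counts} (\linkS4class{BinnedCounts}),
#'   \code{trains} (\linkS4class{SpikeTrainSet} or NULL), \code{spec}, and
#'   \code{clippedFraction} (per-neuron fraction of clipped bins).
#' @examples
#' spec <- SimNetworkSpec(J = 3, mu = log(0.02), duration = 2, seed = 7)
#' sim <- simulateGLMNetwork(spec)
#' colSums(counts(sim$counts))
#' @export
simulateGLMNetwork <- function(spec, returnTrains = TRUE,
                               condition = "other") {
  stopifnot(is(spec, "SimNetworkSpec"))
  J <- spec@J
  K <- as.integer(ceiling(round(spec@duration / spec@binWidth, 9)))
  ids <- sprintf("u%02d", seq_len(J))
  C <- withSeed(spec@seed, {
    m <- matrix(0L, K, J)
    tB <- t(spec@beta)
    p0 <- pmin(exp(spec@mu), 1)
    m[1L, ] <- rbinom(J, 1L, p0)
    clipped <- integer(J)
    prev <- m[1L, ]
    for (k in 2:K) {
      eta <- spec@mu + if (any(prev != 0)) drop(prev %*% tB) else 0
      if (any(!is.finite(eta))) stop("non-finite intensity at bin ", k)
      p <- exp(eta)
      over <- p > 1
      if (any(over)) {
        clipped[over] <- clipped[over] + 1L
        p[over] <- 1
      }
      prev <- rbinom(J, 1L, p)
      m[k, ] <- prev
    }
    attr(m, "clipped") <- clipped
    m
  })
  clipped <- attr(C, "clipped")
  attr(C, "clipped") <- NULL
  clipFrac <- clipped / (K - 1L)
  if (any(clipFrac > 0.001))
    warning("intensity clipped at 1 in > 0.1% of bins for neurons: ",
            paste(ids[clipFrac > 0.001], collapse = ", "))
  colnames(C) <- ids
  bc <- new("BinnedCounts", counts = C, binWidth = spec@binWidth,
            t0 = 0, condition = condition)
  trains <- NULL
  if (returnTrains) {
    st <- lapply(setNames(ids, ids), function(u) {
      k <- which(C[, u] > 0L)
      round((k - 0.5) * spec@binWidth, 6)
    })
    trains <- SpikeTrainSet(st, duration = K * spec@binWidth,
                            condition = condition, unitIds = ids)
  }
  list(counts = bc, trains = trains, spec = spec,
       clippedFraction = setNames(clipFrac, ids))
}

#' Construct a ConditionSeriesSpec
#'
#' @param base a \linkS4class{SimNetworkSpec} giving \code{J}, \code{mu},
#'   bin width and duration (its beta is ignored).
#' @param nConditions number of conditions (default 3: BL, E, BMI/E).
#' @param overlapFraction scalar fraction of links shared between
#'   consecutive conditions, or a length-3 vector of exact pairwise
#'   overlaps (1-2, 2-3, 1-3) for a three-condition series.
#' @param positiveFraction fraction of links with positive coupling
#'   (default 0.7, the majority-excitatory mix of cortical maps).
#' @param connectionCount nonzero links per condition.
#' @param betaRange range of link magnitudes |beta|.
#' @param seed integer seed.
#' @return a \linkS4class{ConditionSeriesSpec}.
#' @export
ConditionSeriesSpec <- function(base, nConditions = 3L,
                                overlapFraction = 0.2,
                                positiveFraction = 0.7,
                                connectionCount, betaRange = c(0.8, 1.5),
                                seed = 1L) {
  new("ConditionSeriesSpec", base = base,
      nConditions = as.integer(nConditions),
      overlapFraction = as.numeric(overlapFraction),
      positiveFraction = as.numeric(positiveFraction),
      connectionCount = as.integer(connectionCount),
      betaRange = as.numeric(betaRange), seed = as.integer(seed))
}

## Draw `n` signed link values with `nPos` positive among them.
drawValues <- function(n, nPos, betaRange) {
  if (n == 0L) return(numeric(0))
  mag <- runif(n, betaRange[1], betaRange[2])
  sgn <- rep(-1, n)
  if (nPos > 0L) sgn[sample.int(n, nPos)] <- 1
  mag * sgn
}

## Off-diagonal linear slot indices of a J x J matrix.
offDiagSlots <- function(J) which(diag(J) == 0)

#' Generate a series of overlapping ground-truth networks
#'
#' Builds one \linkS4class{SimNetworkSpec} per condition, all sharing
#' \code{base}'s baseline rates, with \code{connectionCount} nonzero
#' couplings each and a designed overlap of identical links (position and
#' value) between conditions.
#'
#' With a scalar \code{overlapFraction} \eqn{f}, consecutive conditions
#' share exactly \code{round(f * connectionCount)} links; the remaining
#' links of each new condition are placed uniformly at random among
#' off-diagonal slots not used by the previous condition, so the realized
#' consecutive overlap is exact by construction. With a length-3
#' \code{overlapFraction}, the three pairwise overlaps (1-2, 2-3, 1-3) are
#' planted exactly via disjoint shared-link sets (no link is common to all
#' three conditions).
#'
#' The per-condition sign mix matches \code{positiveFraction} to rounding.
#'
#' @param spec a \linkS4class{ConditionSeriesSpec}.
#' @return list of \linkS4class{SimNetworkSpec}, one per condition.
#' @export
makeConditionSeries <- function(spec) {
  stopifnot(is(spec, "ConditionSeriesSpec"))
  withSeed(spec@seed, {
    if (length(spec@overlapFraction) == 3L) makeTriadSeries(spec)
    else makeChainSeries(spec)
  })
}

makeChainSeries <- function(spec) {
  J <- spec@base@J
  C <- spec@connectionCount
  slots <- offDiagSlots(J)
  nShared <- as.integer(round(spec@overlapFraction * C))
  nPos <- as.integer(round(spec@positiveFraction * C))
  out <- vector("list", spec@nConditions)
  cur <- sample(slots, C)
  val <- drawValues(C, nPos, spec@betaRange)
  out[[1L]] <- seriesMember(spec, cur, val, 1L)
  for (t in seq_len(spec@nConditions - 1L)) {
    keepIdx <- if (nShared > 0L) sample.int(C, nShared) else integer(0)
    free <- setdiff(slots, cur)
    newSlots <- sample(free, C - nShared)
    keptVal <- val[keepIdx]
    keptPos <- sum(keptVal > 0)
    newPos <- min(max(nPos - keptPos, 0L), C - nShared)
    newVal <- drawValues(C - nShared, newPos, spec@betaRange)
    cur <- c(cur[keepIdx], newSlots)
    val <- c(keptVal, newVal)
    out[[t + 1L]] <- seriesMember(spec, cur, val, t + 1L)
  }
  out
}

makeTriadSeries <- function(spec) {
  J <- spec@base@J
  C <- spec@connectionCount
  ov <- spec@overlapFraction           # (1-2, 2-3, 1-3)
  n12 <- as.integer(round(ov[1] * C))
  n23 <- as.integer(round(ov[2] * C))
  n13 <- as.integer(round(ov[3] * C))
  nUniq <- c(C - n12 - n13, C - n12 - n23, C - n23 - n13)
  if (any(nUniq < 0))
    stop("pairwise overlaps exceed connectionCount for some condition")
  need <- n12 + n23 + n13 + sum(nUniq)
  slots <- offDiagSlots(J)
  if (need > length(slots))
    stop("not enough off-diagonal slots for disjoint pairwise overlaps")
  pick <- sample(slots, need)
  splitAt <- cumsum(c(n12, n23, n13, nUniq))
  grp <- Map(function(a, b) pick[seq.int(a, length.out = b)],
             c(1L, splitAt[-length(splitAt)] + 1L),
             c(n12, n23, n13, nUniq))
  names(grp) <- c("s12", "s23", "s13", "u1", "u2", "u3")
  v12 <- drawValues(n12, round(spec@positiveFraction * n12), spec@betaRange)
  v23 <- drawValues(n23, round(spec@positiveFraction * n23), spec@betaRange)
  v13 <- drawValues(n13, round(spec@positiveFraction * n13), spec@betaRange)
  nPos <- as.integer(round(spec@positiveFraction * C))
  uniqVal <- function(nu, sharedVals) {
    posNeeded <- min(max(nPos - sum(sharedVals > 0), 0L), nu)
    drawValues(nu, posNeeded, spec@betaRange)
  }
  v1u <- uniqVal(nUniq[1], c(v12, v13))
  v2u <- uniqVal(nUniq[2], c(v12, v23))
  v3u <- uniqVal(nUniq[3], c(v23, v13))
  list(
    seriesMember(spec, c(grp$s12, grp$s13, grp$u1), c(v12, v13, v1u), 1L),
    seriesMember(spec, c(grp$s12, grp$s23, grp$u2), c(v12, v23, v2u), 2L),
    seriesMember(spec, c(grp$s23, grp$s13, grp$u3), c(v23, v13, v3u), 3L)
  )
}

seriesMember <- function(spec, slots, values, k) {
  J <- spec@base@J
  beta <- matrix(0, J, J)
  beta[slots] <- values
  SimNetworkSpec(J = J, mu = spec@base@mu, beta = beta,
                 binWidth = spec@base@binWidth,
                 duration = spec@base@duration,
                 selfHistory = spec@base@selfHistory,
                 seed = spec@seed + 1000L * k)
}
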