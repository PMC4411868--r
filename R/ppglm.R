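## Point-process GLM fitting: type I (homogeneous Poisson) and type II
## (neighbor-history) models.

#' Construct a ModelSpec
#'
#' @param responseBin response bin width in seconds (0.001 or 0.010 for
#'   the canonical short/long timescales).
#' @param historyWindow history window in seconds; defaults to one
#'   response bin (the canonical one-step history, giving one coefficient
#'   per source at either timescale). Must be an integer multiple of
#'   \code{responseBin}.
#' @param includeSelf include the target's own history (type B model).
#' @param modelType \code{"I"} or \code{"II"}.
#' @return a \linkS4class{ModelSpec}.
#' @export
ModelSpec <- function(responseBin = 0.001, historyWindow = responseBin,
                      includeSelf = FALSE, modelType = "II") {
  new("ModelSpec", responseBin = as.numeric(responseBin),
      historyWindow = as.numeric(historyWindow),
      includeSelf = isTRUE(includeSelf),
      modelType = as.character(modelType))
}

#' Build the regression design for one target neuron
#'
#' Response \code{y[k]} is the target's count in bin \code{k}; the
#' covariate for source \code{j} is that source's spike count summed over
#' the history window of \code{L = historyWindow / responseBin} bins
#' strictly preceding bin \code{k} (the current bin is never included, so
#' lagged history effects are separated from same-bin synchrony). The
#' first \code{L} bins, which lack a full history, are dropped. Column
#' order follows the unit roster; the target column is omitted unless
#' \code{includeSelf} is set.
#'
#' @param binned a \linkS4class{BinnedCounts} whose bin width equals
#'   \code{spec@responseBin}; counts at a finer width are rebinned
#'   automatically when the widths are commensurate.
#' @param target target unit id (or index into the roster).
#' @param spec a \linkS4class{ModelSpec}.
#' @return list with \code{y} (response vector), \code{X} (covariate
#'   matrix, one named column per source), \code{target}, \code{sources},
#'   \code{bins} (original bin index of each response row) and
#'   \code{spec}.
#' @export
buildDesign <- function(binned, target, spec = ModelSpec()) {
  stopifnot(is(binned, "BinnedCounts"), is(spec, "ModelSpec"))
  if (abs(binned@binWidth - spec@responseBin) > 1e-12) {
    if (spec@responseBin < binned@binWidth)
      stop("counts are coarser than the requested response bin")
    binned <- rebinCounts(binned, spec@responseBin)
  }
  C <- binned@counts
  roster <- colnames(C)
  target <- if (is.numeric(target)) roster[target] else as.character(target)
  if (!target %in% roster) stop("unknown target unit: ", target)
  sources <- if (spec@includeSelf) roster else setdiff(roster, target)
  if (length(sources) < 1L)
    stop("type II models need at least one source unit (J >= 2)")
  K <- nrow(C)
  L <- as.integer(round(spec@historyWindow / spec@responseBin))
  if (K <= L) stop("not enough bins for the history window")
  ## lagged window sums via cumulative sums: for response bin k the
  ## covariate is S[k-1] - S[k-1-L], the count in bins (k-L)..(k-1)
  S <- rbind(0, apply(C[, sources, drop = FALSE], 2L, cumsum))
  rows <- (L + 1L):K
  X <- S[rows, , drop = FALSE] - S[rows - L, , drop = FALSE]
  colnames(X) <- sources
  list(y = as.numeric(C[rows, target]), X = X, target = target,
       sources = sources, bins = rows, spec = spec)
}

## Poisson log-likelihood of the intercept-only model (closed form MLE).
interceptLoglik <- function(y) {
  n <- length(y)
  s <- sum(y)
  if (s == 0) return(-Inf)
  rate <- s / n
  s * log(rate) - s - sumLfact(y)
}

#' Fit the type I (homogeneous Poisson) model
#'
#' Closed-form maximum likelihood: the intercept is
#' \code{log(total spikes / total bins)}, with Fisher standard error
#' \code{1 / sqrt(total spikes)}. A target with zero spikes yields a
#' degenerate fit (flagged, excluded downstream) rather than an error.
#'
#' @param binned a \linkS4class{BinnedCounts}.
#' @param target target unit id or index.
#' @return a \linkS4class{NeuronFit} with model type \code{"I"}.
#' @export
fitType1 <- function(binned, target) {
  stopifnot(is(binned, "BinnedCounts"))
  roster <- colnames(binned@counts)
  target <- if (is.numeric(target)) roster[target] else as.character(target)
  y <- as.numeric(binned@counts[, target])
  n <- length(y)
  s <- sum(y)
  if (s == 0) {
    return(new("NeuronFit", target = target, modelType = "I",
               modelSpec = ModelSpec(responseBin = binned@binWidth,
                                     modelType = "I"),
               coef = c("(Intercept)" = -Inf), se = NA_real_,
               cov = matrix(NA_real_, 1, 1), loglik = -Inf,
               nullLoglik = -Inf, converged = TRUE, degenerate = TRUE,
               pValues = NA_real_,
               ci95 = matrix(NA_real_, 1, 2), nObs = as.integer(n),
               spikeCount = 0L, sources = character(0)))
  }
  mu <- log(s / n)
  se <- 1 / sqrt(s)
  ll <- s * mu - s - sumLfact(y)
  z <- mu / se
  new("NeuronFit", target = target, modelType = "I",
      modelSpec = ModelSpec(responseBin = binned@binWidth, modelType = "I"),
      coef = c("(Intercept)" = mu), se = se,
      cov = matrix(se^2, 1, 1), loglik = ll, nullLoglik = ll,
      converged = TRUE, degenerate = FALSE,
      pValues = 2 * pnorm(-abs(z)),
      ci95 = matrix(mu + c(-1, 1) * qnorm(0.975) * se, 1, 2),
      nObs = as.integer(n), spikeCount = as.integer(s),
      sources = character(0))
}

## Newton / IRLS maximizer of the Poisson log-likelihood with log link.
## X includes the intercept column. Step halving guards overshoot; a ridge
## jitter (scaled to the information diagonal) protects against numerical
## rank loss and is applied only when the plain solve fails.
poissonNewton <- function(X, y, tol = 1e-8, maxIter = 100L, ridge = 1e-8,
                          divergeAt = 30) {
  p <- ncol(X)
  lf <- sumLfact(y)
  theta <- c(log(max(mean(y), 1e-12)), rep(0, p - 1L))
  eta <- drop(X %*% theta)
  lam <- exp(eta)
  ll <- sum(y * eta - lam) - lf
  converged <- FALSE
  ridgeUsed <- FALSE
  for (it in seq_len(maxIter)) {
    grad <- drop(crossprod(X, y - lam))
    Xw <- X * sqrt(lam)
    H <- crossprod(Xw)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      ridgeUsed <- TRUE
      step <- solve(H + diag(ridge * (1 + diag(H)), p), grad)
    }
    ## step halving: never accept a decrease in log-likelihood
    fac <- 1
    repeat {
      thetaNew <- theta + fac * step
      etaNew <- drop(X %*% thetaNew)
      lamNew <- exp(etaNew)
      llNew <- sum(y * etaNew - lamNew) - lf
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { thetaNew <- theta; etaNew <- eta
        lamNew <- lam; llNew <- ll; break }
    }
    dll <- abs(llNew - ll) / (abs(ll) + 1)
    theta <- thetaNew; eta <- etaNew; lam <- lamNew; ll <- llNew
    if (max(abs(theta)) > divergeAt) {
      return(list(theta = theta, loglik = ll, converged = FALSE,
                  diverged = TRUE, iter = it, cov = NULL,
                  ridgeUsed = ridgeUsed))
    }
    if (dll < tol) { converged <- TRUE; break }
  }
  Xw <- X * sqrt(lam)
  H <- crossprod(Xw)
  cov <- tryCatch(solve(H), error = function(e) {
    ridgeUsed <<- TRUE
    solve(H + diag(ridge * (1 + diag(H)), p))
  })
  grad <- drop(crossprod(X, y - lam))
  list(theta = theta, loglik = ll, converged = converged, diverged = FALSE,
       iter = it, cov = cov, grad = grad, ridgeUsed = ridgeUsed)
}

#' Fit the type II (neighbor-history) model
#'
#' Maximum-likelihood Poisson regression with log link of the target's
#' per-bin counts on the preceding-history counts of the other units
#' (plus its own, for type B), maximized by Newton iterations with step
#' halving. The coefficient covariance is the inverse observed information
#' at the optimum; confidence intervals and p-values are Wald.
#'
#' Targets with fewer than \code{minSpikes} spikes, non-convergent fits,
#' and fits with a diverging coefficient (perfect separation) are
#' returned flagged (\code{degenerate} and/or \code{converged = FALSE})
#' and are excluded from connectivity maps downstream; they never raise.
#'
#' @param binned a \linkS4class{BinnedCounts}.
#' @param target target unit id or index.
#' @param spec a \linkS4class{ModelSpec}.
#' @param minSpikes minimum target spike count for a usable fit
#'   (default 10; lower-rate cells cannot support history regression).
#' @param maxIter maximum Newton iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a \linkS4class{NeuronFit} with model type \code{"II"}; slot
#'   \code{nullLoglik} holds the intercept-only log-likelihood on the same
#'   response rows (so type II >= null always, the nested-model identity).
#' @examples
#' spec <- SimNetworkSpec(J = 4, mu = log(0.05), duration = 20, seed = 2)
#' sim <- simulateGLMNetwork(spec, returnTrains = FALSE)
#' fit <- fitType2(sim$counts, "u01")
#' fit@coef
#' @export
fitType2 <- function(binned, target, spec = ModelSpec(), minSpikes = 10L,
                     maxIter = 100L, tol = 1e-8) {
  des <- buildDesign(binned, target, spec)
  y <- des$y
  p <- length(des$sources) + 1L
  s <- sum(y)
  nullLL <- interceptLoglik(y)
  blank <- function(converged, degenerate) {
    cf <- setNames(rep(NA_real_, p), c("(Intercept)", des$sources))
    new("NeuronFit", target = des$target, modelType = "II",
        modelSpec = spec, coef = cf,
        se = rep(NA_real_, p), cov = matrix(NA_real_, p, p),
        loglik = NA_real_, nullLoglik = nullLL, converged = converged,
        degenerate = degenerate, pValues = rep(NA_real_, p),
        ci95 = matrix(NA_real_, p, 2), nObs = length(y),
        spikeCount = as.integer(s), sources = des$sources)
  }
  if (s < minSpikes) return(blank(converged = FALSE, degenerate = TRUE))
  X <- cbind(`(Intercept)` = 1, des$X)
  fit <- poissonNewton(X, y, tol = tol, maxIter = as.integer(maxIter))
  if (fit$diverged) return(blank(converged = FALSE, degenerate = TRUE))
  theta <- setNames(fit$theta, colnames(X))
  se <- sqrt(pmax(diag(fit$cov), 0))
  z <- theta / se
  ci <- cbind(theta - qnorm(0.975) * se, theta + qnorm(0.975) * se)
  dimnames(ci) <- list(names(theta), c("lower", "upper"))
  cov <- (fit$cov + t(fit$cov)) / 2
  dimnames(cov) <- list(names(theta), names(theta))
  new("NeuronFit", target = des$target, modelType = "II",
      modelSpec = spec, coef = theta,
      se = setNames(se, names(theta)), cov = cov, loglik = fit$loglik,
      nullLoglik = nullLL, converged = fit$converged, degenerate = FALSE,
      pValues = setNames(2 * pnorm(-abs(z)), names(theta)), ci95 = ci,
      nObs = length(y), spikeCount = as.integer(s), sources = des$sources)
}

#' Significance mask from Wald inference
#'
#' Flags coefficients whose two-sided Wald p-value is below \code{alpha}
#' (equivalently, whose \code{1 - alpha} confidence interval excludes
#' zero). With \code{alpha >= 1} every coefficient is flagged.
#'
#' @param fit a converged \linkS4class{NeuronFit}.
#' @param alpha significance level (default 0.05).
#' @param includeIntercept also return a flag for the intercept.
#' @return named logical vector over the source coefficients (and
#'   optionally the intercept).
#' @export
waldMask <- function(fit, alpha = 0.05, includeIntercept = FALSE) {
  stopifnot(is(fit, "NeuronFit"))
  if (fit@degenerate || !fit@converged)
    stop("waldMask needs a converged, non-degenerate fit")
  pv <- fit@pValues
  flags <- (pv < alpha) | alpha >= 1
  if (!includeIntercept && "(Intercept)" %in% names(flags))
    flags <- flags[setdiff(names(flags), "(Intercept)")]
  flags
}
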