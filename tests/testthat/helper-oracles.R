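## Independent oracles used against the package's own code paths.

## Exact Poisson log-likelihood for a 2-parameter model
## lambda_k = exp(mu + beta * x_k).
exactLoglik2 <- function(theta, y, x) {
  eta <- theta[1] + theta[2] * x
  sum(y * eta - exp(eta)) - sum(lfactorial(y))
}

## Brute-force MLE of (mu, beta): coarse grid search followed by cyclic
## golden-section refinement of each coordinate. Independent of the
## package's Newton fitter.
gridPoissonMLE <- function(y, x, muRange = c(-8, 3), betaRange = c(-6, 6)) {
  grid_mu <- seq(muRange[1], muRange[2], length.out = 120)
  grid_be <- seq(betaRange[1], betaRange[2], length.out = 120)
  best <- c(NA, NA); bestll <- -Inf
  for (m in grid_mu) for (b in grid_be) {
    ll <- exactLoglik2(c(m, b), y, x)
    if (ll > bestll) { bestll <- ll; best <- c(m, b) }
  }
  golden <- function(f, lo, hi, tol = 1e-9) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- f(c1); f2 <- f(c2)
    while (b - a > tol) {
      if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- f(c2)
      } else { b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- f(c1) }
    }
    (a + b) / 2
  }
  span_mu <- diff(grid_mu[1:2]) * 2
  span_be <- diff(grid_be[1:2]) * 2
  for (round in 1:60) {
    best[1] <- golden(function(m) exactLoglik2(c(m, best[2]), y, x),
                      best[1] - span_mu, best[1] + span_mu)
    best[2] <- golden(function(b) exactLoglik2(c(best[1], b), y, x),
                      best[2] - span_be, best[2] + span_be)
    span_mu <- span_mu / 2 + 1e-7
    span_be <- span_be / 2 + 1e-7
  }
  list(theta = best, loglik = exactLoglik2(best, y, x))
}

## Two-sided exact binomial p-value under p = 0.5 by full enumeration of
## outcome masses (minimum-likelihood summation).
enumBinomTwoSided <- function(kept, total) {
  mass <- choose(total, 0:total) / 2^total
  sum(mass[mass <= mass[kept + 1] * (1 + 1e-12)])
}

## Gamma-renewal spike train: ISIs ~ Gamma(shape, mean = 1 / rateHz).
rGammaRenewal <- function(shape, rateHz, duration) {
  n <- ceiling(duration * rateHz * 2 + 50)
  isi <- rgamma(n, shape = shape, rate = shape * rateHz)
  tt <- cumsum(isi)
  tt[tt < duration]
}

## Wrap a plain count matrix as BinnedCounts.
bcFromMatrix <- function(m, binWidth = 0.001, condition = "other") {
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("u%02d", seq_len(ncol(m)))
  new("BinnedCounts", counts = m, binWidth = binWidth, t0 = 0,
      condition = condition)
}

## Minimal hand-built type II NeuronFit (for pure map-assembly tests).
mkFit <- function(target, sources, coef, se, converged = TRUE,
                  degenerate = FALSE, responseBin = 0.001) {
  p <- length(sources) + 1L
  cf <- setNames(c(0, coef), c("(Intercept)", sources))
  sev <- setNames(c(1, se), names(cf))
  z <- cf / sev
  new("NeuronFit", target = target, modelType = "II",
      modelSpec = ModelSpec(responseBin = responseBin),
      coef = cf, se = sev, cov = diag(sev^2),
      loglik = -1, nullLoglik = -2, converged = converged,
      degenerate = degenerate,
      pValues = setNames(2 * pnorm(-abs(z)), names(cf)),
      ci95 = cbind(cf - qnorm(0.975) * sev, cf + qnorm(0.975) * sev),
      nObs = 100L, spikeCount = 10L, sources = sources)
}

## Binary map from a plain 0/1 matrix.
mkBinary <- function(m, condition = "other", includeSelf = FALSE) {
  if (is.null(rownames(m)) && !is.null(colnames(m)))
    rownames(m) <- colnames(m)
  new("BinaryMap", links = m, condition = condition,
      includeSelf = includeSelf)
}
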