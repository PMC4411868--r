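test_that("the design lags source counts strictly before the response bin", {
  m <- cbind(u1 = c(0L, 1L, 0L, 1L), u2 = c(1L, 0L, 1L, 0L))
  bc <- bcFromMatrix(m, binWidth = 0.001)
  des <- buildDesign(bc, "u1", ModelSpec(responseBin = 0.001))
  expect_equal(des$y, c(1, 0, 1))               # bins 2..4 of the target
  expect_equal(as.vector(des$X), c(1, 0, 1))    # u2 shifted by one bin
  expect_equal(des$sources, "u2")

  ## type B keeps the target's own history: one covariate per unit
  desB <- buildDesign(bc, "u1", ModelSpec(responseBin = 0.001,
                                          includeSelf = TRUE))
  expect_equal(ncol(desB$X), 2L)
  expect_equal(as.vector(desB$X[, "u1"]), c(0, 1, 0))

  ## W = 2 bins: covariate is the hand-computed sum of the two
  ## preceding bins on a 6-bin toy
  m6 <- cbind(u1 = c(0L, 0L, 1L, 0L, 1L, 0L),
              u2 = c(1L, 1L, 0L, 2L, 0L, 1L))
  bc6 <- bcFromMatrix(m6, binWidth = 0.001)
  des2 <- buildDesign(bc6, "u1", ModelSpec(responseBin = 0.001,
                                           historyWindow = 0.002))
  expect_equal(des2$y, c(1, 0, 1, 0))           # bins 3..6
  expect_equal(as.vector(des2$X), c(1 + 1, 1 + 0, 0 + 2, 2 + 0))

  ## 10 ms model on 1 ms counts: response is rebinned first
  m10 <- matrix(rbinom(400, 1, 0.2), 200, 2,
                dimnames = list(NULL, c("u1", "u2")))
  des10 <- buildDesign(bcFromMatrix(m10, 0.001), "u1",
                       ModelSpec(responseBin = 0.010))
  expect_length(des10$y, 19L)
  expect_error(buildDesign(bcFromMatrix(m10[, 1, drop = FALSE], 0.001),
                           "u1", ModelSpec(responseBin = 0.001)),
               "source")
})

test_that("type I fits are the closed-form Poisson MLE", {
  m <- matrix(0L, 1000, 2, dimnames = list(NULL, c("u1", "u2")))
  m[seq_len(100) * 10, 1] <- 1L
  bc <- bcFromMatrix(m)
  fit <- fitType1(bc, "u1")
  expect_identical(unname(fit@coef), log(0.1))
  expect_true(fit@converged)
  expect_equal(fit@se, 1 / sqrt(100))

  ones <- bcFromMatrix(matrix(1L, 50, 1, dimnames = list(NULL, "u1")))
  expect_identical(unname(fitType1(ones, "u1")@coef), 0)

  z <- fitType1(bc, "u2")
  expect_true(z@degenerate)
  expect_identical(unname(z@coef), -Inf)
})

test_that("the Newton fitter matches a brute-force likelihood search", {
  ## hand-written 12-bin, 2-unit data; the counts are laid out so that
  ## the built design is exactly (y, x)
  y <- c(0, 1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 1)
  x <- c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1, 0, 0)
  m <- cbind(u1 = c(0L, as.integer(y)), u2 = c(as.integer(x), 0L))
  bc <- bcFromMatrix(m)
  des <- buildDesign(bc, "u1", ModelSpec(responseBin = 0.001))
  expect_equal(des$y, y)
  expect_equal(as.vector(des$X), x)

  fit <- fitType2(bc, "u1", minSpikes = 1L)
  oracle <- gridPoissonMLE(y, x)
  expect_true(fit@converged)
  expect_lt(abs(fit@coef[["(Intercept)"]] - oracle$theta[1]), 1e-4)
  expect_lt(abs(fit@coef[["u2"]] - oracle$theta[2]), 1e-4)
  expect_lt(abs(fit@loglik - oracle$loglik), 1e-6)
})

test_that("the Newton fitter agrees with an independent IRLS implementation", {
  spec <- SimNetworkSpec(J = 5, mu = log(0.05),
                         beta = {b <- matrix(0, 5, 5); b[1, 3] <- 1.2
                                 b[2, 1] <- -0.8; b},
                         duration = 30, seed = 13)
  sim <- simulateGLMNetwork(spec, returnTrains = FALSE)
  for (u in c("u01", "u02")) {
    fit <- fitType2(sim$counts, u)
    des <- buildDesign(sim$counts, u, ModelSpec(responseBin = 0.001))
    ref <- glm(des$y ~ des$X, family = poisson())
    expect_equal(unname(fit@coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit@se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
    expect_equal(fit@loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    ## score at the optimum vanishes
    lam <- exp(drop(cbind(1, des$X) %*% fit@coef))
    expect_lt(max(abs(crossprod(cbind(1, des$X), des$y - lam))), 1e-4)
    ## nested-model ordering
    expect_gte(fit@loglik, fit@nullLoglik)
  }
})

test_that("degenerate targets and all-zero covariates take the safe paths", {
  set.seed(8)
  m <- cbind(u1 = rbinom(5000, 1, 0.03), u2 = 0L, u3 = 0L)
  bc <- bcFromMatrix(m)
  ## all covariates identically zero: the history model collapses to the
  ## type I intercept on the same response rows (ridge-protected solve)
  fit <- fitType2(bc, "u1")
  expect_true(fit@converged)
  expect_equal(fit@coef[["u2"]], 0, tolerance = 1e-8)
  expect_equal(fit@coef[["u3"]], 0, tolerance = 1e-8)
  sub <- fitType1(bcFromMatrix(m[-1, "u1", drop = FALSE]), "u1")
  expect_equal(fit@coef[["(Intercept)"]], unname(sub@coef),
               tolerance = 1e-8)
  expect_equal(fit@loglik, sub@loglik, tolerance = 1e-8)
  expect_equal(fit@nullLoglik, sub@loglik, tolerance = 1e-10)

  ## too few spikes: flagged, not crashed
  low <- fitType2(bc, "u2")
  expect_true(low@degenerate)
  expect_false(low@converged)
  expect_true(all(is.na(low@coef)))
})

test_that("fits are invariant to unit roster permutation", {
  spec <- SimNetworkSpec(J = 4, mu = log(0.04),
                         beta = {b <- matrix(0, 4, 4); b[2, 4] <- 1; b},
                         duration = 20, seed = 19)
  sim <- simulateGLMNetwork(spec, returnTrains = FALSE)
  m <- counts(sim$counts)
  perm <- c(3, 1, 4, 2)
  bcP <- bcFromMatrix(m[, perm], binWidth = 0.001)
  f1 <- fitType2(sim$counts, "u02")
  f2 <- fitType2(bcP, "u02")
  expect_equal(f1@coef[names(f2@coef)], f2@coef, tolerance = 1e-9)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-10)
})

test_that("Wald masks flag exactly the coefficients away from zero", {
  fit <- mkFit("u1", c("a", "b", "c"), coef = c(0, 1.0, -0.05),
               se = c(0.2, 0.1, 0.3))
  m <- waldMask(fit, 0.05)
  expect_equal(m, c(a = FALSE, b = TRUE, c = FALSE))
  expect_true(all(waldMask(fit, 1)))
  expect_false(any(waldMask(fit, 1e-30)))
  bad <- mkFit("u1", "a", 1, 1, converged = FALSE)
  expect_error(waldMask(bad), "converged")
})
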