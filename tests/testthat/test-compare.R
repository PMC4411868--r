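test_that("shared-connection fractions follow each denominator", {
  set.seed(3)
  m <- matrix(rbinom(64, 1, 0.4), 8, 8); diag(m) <- 0
  A <- mkBinary(m, "BL")
  for (den in c("symmetric", "union", "of_first"))
    expect_equal(sharedConnections(A, A, den)$common_fraction, 1.0)

  d1 <- matrix(0, 8, 8); d1[1, 2] <- d1[2, 3] <- 1
  d2 <- matrix(0, 8, 8); d2[3, 1] <- d2[4, 5] <- 1
  expect_equal(sharedConnections(mkBinary(d1), mkBinary(d2))$common_fraction, 0)

  ## n_a = 20, n_b = 30, n_common = 10
  a <- matrix(0, 10, 10); a[cbind(rep(1:5, 4), rep(6:9, each = 5))] <- 1
  stopifnot(sum(a) == 20)
  b <- matrix(0, 10, 10)
  b[cbind(rep(1:5, 2), rep(6:7, each = 5))] <- 1   # 10 common with a
  b[cbind(rep(6:9, each = 5), rep(1:5, 4))] <- 1   # 20 disjoint
  stopifnot(sum(b) == 30, sum(a * b) == 10)
  expect_equal(sharedConnections(mkBinary(a), mkBinary(b),
                                 "symmetric")$common_fraction, 0.4)
  expect_equal(sharedConnections(mkBinary(a), mkBinary(b),
                                 "union")$common_fraction, 0.25)
  expect_equal(sharedConnections(mkBinary(a), mkBinary(b),
                                 "of_first")$common_fraction, 0.5)

  ## symmetry holds for symmetric/union, not for of_first
  A2 <- mkBinary(a); B2 <- mkBinary(b)
  for (den in c("symmetric", "union"))
    expect_equal(sharedConnections(A2, B2, den)$common_fraction,
                 sharedConnections(B2, A2, den)$common_fraction)
  expect_false(isTRUE(all.equal(
    sharedConnections(A2, B2, "of_first")$common_fraction,
    sharedConnections(B2, A2, "of_first")$common_fraction)))

  expect_error(sharedConnections(mkBinary(a), mkBinary(d1)), "shape")
})

test_that("the exact binomial change test equals full enumeration", {
  ## spot value: keeping 5 of 20 links
  expect_equal(binomialChangeTest(5, 20), 2 * 21700 / 2^20,
               tolerance = 1e-12)
  for (total in c(1:10, 15, 20)) for (kept in 0:total)
    expect_equal(binomialChangeTest(kept, total),
                 enumBinomTwoSided(kept, total), tolerance = 1e-12)
  expect_equal(binomialChangeTest(10, 20), 1.0)
  expect_equal(binomialChangeTest(0, 1), 1.0)
  expect_error(binomialChangeTest(5, 0), "total")
  expect_error(binomialChangeTest(7, 5), "kept")
})

test_that("persistence matrices are symmetric with unit diagonal", {
  set.seed(9)
  m <- matrix(rbinom(100, 1, 0.35), 10, 10); diag(m) <- 0
  same <- lapply(1:3, function(i) mkBinary(m, sprintf("BL%d", i)))
  P <- persistenceMatrix(same)
  expect_equal(unname(P), matrix(1, 3, 3))

  two <- persistenceMatrix(list(mkBinary(m, "a"),
                                mkBinary(1 - diag(10), "b")))
  expect_equal(dim(two), c(2L, 2L))
  expect_equal(two["a", "b"], two["b", "a"])
  expect_equal(diag(two), c(a = 1, b = 1))

  ## drift chain: entries decay away from the diagonal on average
  drift <- list(m)
  cur <- m
  for (t in 2:6) {
    idxOn <- which(cur == 1)
    offDiag <- setdiff(which(cur == 0), which(diag(10) == 1))
    cur[sample(idxOn, 6)] <- 0
    cur[sample(offDiag, 6)] <- 1
    drift[[t]] <- cur
  }
  P <- persistenceMatrix(lapply(seq_along(drift), function(i)
    mkBinary(drift[[i]], sprintf("t%d", i))))
  lag1 <- mean(P[cbind(1:5, 2:6)])
  lag4 <- mean(P[cbind(1:2, 5:6)])
  expect_gt(lag1, lag4)
})

test_that("common-strength correlation isolates persistent links", {
  roster <- sprintf("u%d", 1:6)
  bm <- function(entries) {
    b <- matrix(0, 6, 6, dimnames = list(roster, roster))
    for (e in entries) b[e[[1]], e[[2]]] <- e[[3]]
    new("ConnectivityMap", beta = b,
        fittedMask = setNames(rep(TRUE, 6), roster), condition = "x",
        modelSpec = ModelSpec(), alpha = 0.05)
  }
  A <- bm(list(list(1, 2, 0.5), list(2, 3, -0.4), list(3, 4, 1.0),
               list(5, 6, 0.8)))
  B <- bm(list(list(1, 2, 1.0), list(2, 3, -0.8), list(3, 4, 2.0),
               list(4, 5, 0.3)))
  cs <- commonStrengthCorrelation(A, B)
  expect_equal(cs$n_common, 3)
  expect_equal(cs$strength_r, 1.0)            # beta_b = 2 * beta_a
  expect_setequal(cs$table$status[cs$table$status != "both"],
                  c("only_a", "only_b"))

  ## one common link: correlation undefined, table still produced
  C <- bm(list(list(1, 2, 0.7)))
  csC <- commonStrengthCorrelation(A, C)
  expect_true(is.na(csC$strength_r))
  expect_equal(nrow(csC$table), 4)

  ## persistent core with 10% strength noise stays highly correlated
  set.seed(44)
  core <- runif(20, 0.5, 1.5) * sample(c(-1, 1), 20, TRUE, c(0.3, 0.7))
  roster2 <- sprintf("v%02d", 1:10)
  mk <- function(vals) {
    b <- matrix(0, 10, 10, dimnames = list(roster2, roster2))
    slots <- which(upper.tri(b))[1:20]
    b[slots] <- vals
    new("ConnectivityMap", beta = b,
        fittedMask = setNames(rep(TRUE, 10), roster2), condition = "x",
        modelSpec = ModelSpec(), alpha = 0.05)
  }
  r <- commonStrengthCorrelation(
    mk(core + rnorm(20, 0, 0.1 * abs(core))),
    mk(core + rnorm(20, 0, 0.1 * abs(core))))$strength_r
  expect_gt(r, 0.9)
})

test_that("session aggregation summarizes pairs and tests orderings", {
  same <- data.frame(session = rep(1:6, 2),
                     pair = rep(c("E-BMI/E", "BL-E"), each = 6),
                     common_fraction = rep(0.2, 12))
  agS <- aggregateSessions(same)
  expect_equal(agS$signed_rank_p, 1)

  up <- data.frame(session = rep(1:6, 2),
                   pair = rep(c("E-BMI/E", "BL-E"), each = 6),
                   common_fraction = c(seq(0.25, 0.30, length.out = 6),
                                       seq(0.12, 0.17, length.out = 6)))
  agU <- aggregateSessions(up)
  expect_lt(agU$signed_rank_p, 0.05)
  expect_equal(sort(agU$summary$pair), c("BL-E", "E-BMI/E"))
  expect_equal(agU$summary$n, c(6, 6))

  single <- up[up$session == 1, ]
  agOne <- aggregateSessions(single)
  expect_true(is.na(agOne$signed_rank_p))
  expect_match(agOne$note, "skipped")
  expect_error(aggregateSessions(up[, 1:2]), "columns")
})
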