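test_that("map assembly respects masks, gating and orientation", {
  roster <- c("u1", "u2", "u3")
  fits <- list(
    u1 = mkFit("u1", c("u2", "u3"), coef = c(1.2, 0.01), se = c(0.1, 0.5)),
    u2 = mkFit("u2", c("u1", "u3"), coef = c(-0.9, 0), se = c(0.1, 0.2)),
    u3 = mkFit("u3", c("u1", "u2"), coef = c(5, 5), se = c(0.1, 0.1),
               converged = FALSE)
  )
  map <- buildConnectivityMap(fits, roster, condition = "BL")
  ## row = target, column = source
  expect_equal(map@beta["u1", "u2"], 1.2)
  expect_equal(map@beta["u2", "u1"], -0.9)
  expect_equal(map@beta["u1", "u3"], 0)      # CI crosses zero
  expect_equal(sum(map@beta["u3", ] != 0), 0)  # non-converged row zeroed
  expect_false(map@fittedMask["u3"])

  ## GOF gating empties the rows of rejected targets
  gated <- buildConnectivityMap(fits, roster, wellFitted = "u2")
  expect_equal(sum(gated@beta != 0), 1)
  expect_equal(gated@beta["u2", "u1"], -0.9)

  ## order independence over targets
  map2 <- buildConnectivityMap(fits[c(3, 1, 2)], roster, condition = "BL")
  expect_identical(map@beta, map2@beta)

  ## no significant coefficients: the zero matrix, not an error
  weak <- list(u1 = mkFit("u1", c("u2", "u3"), c(0.05, 0), c(1, 1)))
  expect_equal(sum(buildConnectivityMap(weak, roster)@beta != 0), 0)

  expect_error(buildConnectivityMap(fits, roster[1:2]), "roster")
})

test_that("a planted one-way coupling lands at (target row, source column)", {
  b <- matrix(0, 4, 4); b[2, 3] <- 1.5       # u03 drives u02
  spec <- SimNetworkSpec(J = 4, mu = log(0.03), beta = b,
                         duration = 60, seed = 9)
  sim <- simulateGLMNetwork(spec, returnTrains = FALSE)
  roster <- unitIds(sim$counts)
  fits <- lapply(setNames(roster, roster),
                 function(u) fitType2(sim$counts, u))
  map <- buildConnectivityMap(fits, roster)
  expect_true(map@beta["u02", "u03"] != 0)
  expect_equal(map@beta["u03", "u02"], 0)
})

test_that("density, Q and sign summaries follow their definitions", {
  m <- matrix(0, 4, 4); m[1, 2] <- m[2, 3] <- m[4, 1] <- 1
  expect_equal(connectionDensity(mkBinary(m)), 0.25)
  full <- 1 - diag(4)
  expect_equal(connectionDensity(mkBinary(full)), 1)
  expect_equal(connectionDensity(mkBinary(matrix(0, 4, 4))), 0)
  ## self-links allowed: denominator J^2
  expect_equal(connectionDensity(mkBinary(diag(4), includeSelf = TRUE)),
               0.25)

  expect_equal(qMetric(0.15, 0.09), 0.5)
  expect_equal(qMetric(0.3, 1), 0.3)
  expect_equal(qMetric(0, 0.5), 0)
  expect_warning(expect_true(is.na(qMetric(0.2, 0))), "undefined")

  ## Q strictly decreases as links are added at fixed n
  q <- vapply(c(0.1, 0.2, 0.4, 0.8), function(d) qMetric(0.15, d),
              numeric(1))
  expect_true(all(diff(q) < 0))

  fits <- list(u1 = mkFit("u1", c("u2", "u3"), c(0.5, 1.5), c(0.01, 0.01)),
               u2 = mkFit("u2", c("u1", "u3"), c(-1.0, 0), c(0.01, 1)))
  map <- buildConnectivityMap(fits, c("u1", "u2", "u3"))
  ss <- signSummary(map)
  expect_equal(ss$n_pos, 2)
  expect_equal(ss$n_neg, 1)
  expect_equal(ss$mean_pos, 1.0)
  expect_equal(ss$mean_neg, -1.0)
  expect_equal(ss$neg_pos_ratio, 0.5)

  allPos <- buildConnectivityMap(fits["u1"], c("u1", "u2", "u3"))
  expect_equal(signSummary(allPos)$n_neg, 0)
  expect_true(is.na(signSummary(allPos)$mean_neg))
})

test_that("density of a union dominates both parts", {
  set.seed(14)
  for (i in 1:10) {
    a <- matrix(rbinom(36, 1, 0.3), 6, 6); diag(a) <- 0
    b <- matrix(rbinom(36, 1, 0.3), 6, 6); diag(b) <- 0
    u <- pmax(a, b)
    expect_gte(connectionDensity(mkBinary(u)),
               max(connectionDensity(mkBinary(a)),
                   connectionDensity(mkBinary(b))))
  }
})

test_that("GraphML export round-trips the weighted directed edges", {
  fits <- list(u1 = mkFit("u1", c("u2", "u3"), c(1.2, 0), c(0.05, 1)),
               u3 = mkFit("u3", c("u1", "u2"), c(-0.7, 0), c(0.05, 1)))
  map <- buildConnectivityMap(fits, c("u1", "u2", "u3"))
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(map, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  expect_setequal(sprintf("%s>%s:%g", el[, 1], el[, 2], w),
                  c("u2>u1:1.2", "u1>u3:-0.7"))
})
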