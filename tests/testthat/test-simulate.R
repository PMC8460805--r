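test_that("the integrator is exact for zero drift and noise, and seeded", {
  m <- sdeModel(drift = function(x, t) 0 * x, noise = function(x, t) 0,
                dim = 2L)
  tr <- eulerMaruyama(m, c(1, -2), dt = 0.1, nSteps = 50, seed = 1)
  expect_true(all(tr[, 1] == 1 & tr[, 2] == -2))
  m2 <- sdeModel(drift = function(x, t) -x, noise = function(x, t) 0.5,
                 dim = 1L)
  a <- eulerMaruyama(m2, 0, dt = 0.01, nSteps = 1000, seed = 7)
  b <- eulerMaruyama(m2, 0, dt = 0.01, nSteps = 1000, seed = 7)
  expect_identical(a, b)
})

test_that("Ornstein-Uhlenbeck variance matches the closed form", {
  theta <- 2; eps <- 0.3
  m <- sdeModel(drift = function(x, t) -theta * x,
                noise = function(x, t) sqrt(2 * eps), dim = 1L)
  tr <- eulerMaruyama(m, 0, dt = 5e-3, nSteps = 2e5, seed = 8)
  x <- tr[-(1:2e4), 1]
  v <- var(x)
  vTrue <- eps / theta
  # autocorrelation-adjusted standard error of the variance estimate
  tauC <- 1 / (theta * 5e-3)
  se <- vTrue * sqrt(2 * 2 * tauC / length(x))
  expect_lt(abs(v - vTrue), 3 * se)
})

test_that("a potential inconsistent with the drift is rejected", {
  expect_error(
    sdeModel(drift = function(x, t) x, noise = function(x, t) 1, dim = 1L,
             potential = function(x) sum(x^2) / 2),
    "-grad")
})

test_that("the triple-well potential has the advertised critical points", {
  pot <- tripleWellPotential()
  U <- pot@potential
  g <- function(z) -pot@drift(z, 0)
  for (r in seq_len(3)) {
    expect_lt(sqrt(sum(g(pot@minima[r, ])^2)), 1e-5)
    expect_lt(sqrt(sum(g(pot@saddles[r, ])^2)), 1e-5)
  }
  uMin <- apply(pot@minima, 1, U)
  uSad <- apply(pot@saddles, 1, U)
  expect_lt(diff(range(uMin)), 1e-8)   # three-fold symmetry
  expect_lt(diff(range(uSad)), 1e-8)
  expect_gt(min(uSad), max(uMin))      # saddles above the minima
  expect_gt(U(c(0, 0)), max(uSad))     # order-2 saddle above the saddles
  expect_equal(pot@barrier, uSad[1] - uMin[1])
})

test_that("triple-well occupancies are near-symmetric at moderate noise", {
  ds <- simulateTripleWell(epsilon = 0.45, nCells = 2001, seed = 5)
  expect_identical(nrow(ds@coords), 2001L)
  frac <- tabulate(ds@attractor, 3) / 2001
  expect_true(all(frac > 0.15))
  expect_true(all(c("core", "saddle", "transition-layer") %in% ds@region))
})

test_that("larger noise produces more inter-basin hops", {
  hops <- vapply(c(0.35, 0.8), function(eps) {
    ds <- simulateTripleWell(epsilon = eps, nCells = 1000, nSteps = 60000,
                             seed = 51)
    sum(diff(ds@attractor) != 0)
  }, numeric(1))
  expect_gt(hops[2], hops[1])
})

test_that("noiseless fold dynamics switch only past the bifurcation point", {
  ds <- simulateSaddleNode(noise = 0, nCells = 500, seed = 1)
  x <- ds@coords[, 1]
  s <- ds@params$signalValues
  swit <- which(x < 0)[1]
  expect_false(is.na(swit))
  expect_lt(s[swit], ds@params$sFold)
  # with noise the switch precedes the deterministic fold on average
  sw <- vapply(1:6, function(sd) {
    d <- simulateSaddleNode(nCells = 500, seed = sd)
    d@params$signalValues[which(d@coords[, 1] < 0)[1]]
  }, numeric(1))
  expect_gt(mean(sw), ds@params$sFold)
})

test_that("saddle-node datasets carry consistent ground truth", {
  ds <- simulateSaddleNode(nCells = 2000, seed = 3)
  expect_identical(nrow(ds@coords), 2000L)
  expect_true(all(ds@attractor %in% 1:2))
  # upper-branch cores sit high, lower-branch cores sit low
  up <- ds@region == "core" & ds@attractor == 1L
  lo <- ds@region == "core" & ds@attractor == 2L
  expect_gt(min(ds@coords[up, 1]), 0.4)
  expect_lt(max(ds@coords[lo, 1]), -0.6)
})

test_that("simulators are bit-reproducible given their seed", {
  a <- simulateTripleWell(nCells = 200, nSteps = 5000, seed = 9)
  b <- simulateTripleWell(nCells = 200, nSteps = 5000, seed = 9)
  expect_identical(a@coords, b@coords)
  expect_identical(a@attractor, b@attractor)
  c1 <- simulateSaddleNode(nCells = 200, seed = 10)
  c2 <- simulateSaddleNode(nCells = 200, seed = 10)
  expect_identical(c1@coords, c2@coords)
})

test_that("small-noise basin occupancies follow the Boltzmann weights", {
  # equal wells: each basin gets about a third of the samples
  ds <- simulateTripleWell(epsilon = 0.4, nCells = 1500, nSteps = 150000,
                           seed = 52)
  frac <- tabulate(ds@attractor, 3) / 1500
  expect_true(all(abs(frac - 1 / 3) < 0.2))
})

test_that("toy chains have their advertised structure", {
  rw <- toyReversibleChain("birth-death", 6, seed = 53)
  w <- affinityMatrix(rw)
  offtri <- w[abs(row(w) - col(w)) > 1]
  expect_true(all(offtri == 0))
  rwr <- toyReversibleChain("random", 9, seed = 54)
  mu <- stationaryDist(rwr)
  p <- transitionMatrix(rwr)
  expect_lt(max(abs(mu * p - t(mu * p))), 1e-12)
  rwb <- toyReversibleChain("block", 10, seed = 55)
  expect_lt(coarseObjective(attr(rwb, "blockLabels"), transitionMatrix(rwb),
                            stationaryDist(rwb))$J, 1e-12)
})
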