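test_that("Hilbert-Schmidt distance matches the naive loop and its limits", {
  set.seed(7)
  a <- matrix(runif(9), 3, 3)
  b <- matrix(runif(9), 3, 3)
  mu <- runif(3, 0.5, 1)
  expect_lt(abs(hsDistance(a, b, mu) - bruteHs(a, b, mu)), 1e-12)
  expect_equal(hsDistance(a, a, mu), 0)
  # uniform mu cancels the weights: plain squared Frobenius distance
  muU <- rep(1 / 3, 3)
  expect_equal(hsDistance(a, b, muU), sum((a - b)^2))
  expect_error(hsDistance(a, b[1:2, 1:2], mu), "shape")
})

test_that("induced walk reduces correctly in the degenerate limits", {
  rw <- toyReversibleChain("random", 6, seed = 8)
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  # K = N with phat = p reproduces p exactly
  expect_lt(max(abs(inducedWalk(1:6, p, mu) - p)), 1e-12)
  # K = 1 forces the rank-one equilibrium kernel
  p1 <- inducedWalk(rep(1L, 6), matrix(1, 1, 1), mu)
  expect_lt(max(abs(p1 - matrix(mu, 6, 6, byrow = TRUE))), 1e-12)
})

test_that("induced walk matches hand evaluation on a 4-cell toy", {
  mu <- c(0.1, 0.2, 0.3, 0.4)
  labels <- c(1L, 1L, 2L, 2L)
  phat <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  got <- inducedWalk(labels, phat, mu)
  muHat <- c(0.3, 0.7)
  man <- matrix(0, 4, 4)
  for (x in 1:4) for (y in 1:4)
    man[x, y] <- phat[labels[x], labels[y]] * mu[y] / muHat[labels[y]]
  expect_lt(max(abs(got - man)), 1e-12)
  expect_lt(max(abs(rowSums(got) - 1)), 1e-12)
})

test_that("optimal phat matches a simplex-constrained numerical minimizer", {
  # 4-state reversible chain, blocks {1,2} and {3,4}
  rw <- toyReversibleChain("random", 4, seed = 9)
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  labels <- c(1L, 1L, 2L, 2L)
  closed <- optimalPhat(labels, p, mu)
  # oracle: optimize both rows through softmax parameterization
  obj <- function(theta) {
    ph <- rbind(exp(theta[1:2]) / sum(exp(theta[1:2])),
                exp(theta[3:4]) / sum(exp(theta[3:4])))
    hsDistance(inducedWalk(labels, ph, mu), p, mu)
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  num <- rbind(exp(opt$par[1:2]) / sum(exp(opt$par[1:2])),
               exp(opt$par[3:4]) / sum(exp(opt$par[3:4])))
  expect_lt(max(abs(closed - num)), 1e-6)
  expect_equal(unname(rowSums(closed)), c(1, 1))
  # block-aggregated objective equals the dense evaluation
  co <- coarseObjective(labels, p, mu)
  expect_lt(abs(co$J - hsDistance(inducedWalk(labels, closed, mu), p, mu)),
            1e-10)
})

test_that("exact lumpability is recovered with J = 0", {
  rw <- toyReversibleChain("block", 12, seed = 10, nBlocks = 3L)
  labels <- attr(rw, "blockLabels")
  co <- coarseObjective(labels, transitionMatrix(rw), stationaryDist(rw))
  expect_lt(co$J, 1e-12)
  expect_lt(max(abs(co$phat - attr(rw, "blockPhat"))), 1e-10)
  cg <- optimizePartition(rw, 3, seed = 1)
  expect_lt(cg@objective, 1e-12)
})

test_that("block-diagonal walks coarse-grain to the identity", {
  set.seed(11)
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 0.5
  w[4:6, 4:6] <- 0.5
  diag(w) <- 0
  d <- rowSums(w)
  p <- w / d
  mu <- d / sum(d)
  expect_equal(optimalPhat(c(1L, 1L, 1L, 2L, 2L, 2L), p, mu), diag(2))
})

test_that("partition optimizer attains the brute-force bipartition optimum", {
  # N = 8 random reversible chains; enumerate all 127 nonempty bipartitions
  for (seed in c(1, 2, 3)) {
    rw <- toyReversibleChain("random", 8, seed = seed)
    p <- transitionMatrix(rw)
    mu <- stationaryDist(rw)
    best <- Inf
    for (mask in 1:127) {
      labels <- as.integer(intToBits(mask))[1:8] + 1L
      best <- min(best, coarseObjective(labels, p, mu, K = 2L)$J)
    }
    cg <- optimizePartition(rw, 2, seed = 1)
    expect_lt(cg@objective, best + 1e-10)
  }
})

test_that("objective trace is non-increasing and model is valid", {
  rw <- toyReversibleChain("random", 30, seed = 12)
  cg <- optimizePartition(rw, 3, seed = 2)
  expect_true(all(diff(cg@trace) <= 1e-12))
  expect_true(methods::validObject(cg))
  # coarse detailed balance inherited from the reversible fine walk
  fl <- cg@muHat * cg@phat
  expect_lt(max(abs(fl - t(fl))), 1e-8)
})

test_that("noisier triple-well dynamics raise off-diagonal coarse mass", {
  offmass <- vapply(c(0.35, 0.8), function(eps) {
    ds <- simulateTripleWell(epsilon = eps, nCells = 500, nSteps = 50000,
                             seed = 13)
    rw <- buildRandomWalk(buildAffinity(ds@coords, 15))
    cg <- optimizePartition(rw, 3, seed = 1)
    mean(1 - diag(cg@phat))
  }, numeric(1))
  expect_gt(offmass[2], offmass[1])
})
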