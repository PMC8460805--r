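test_that("committors satisfy boundary conditions and simple symmetries", {
  # K = 2 boundary-only case
  phat <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  muHat <- c(2 / 3, 1 / 3)
  q <- committors(phat, muHat, 1, 2)
  expect_equal(q$qPlus, c(0, 1))
  expect_equal(q$qMinus, c(1, 0))
  # symmetric 3-state path chain: midpoint committor is 1/2
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[2, 3] <- w[3, 2] <- 1
  rw <- buildRandomWalk(w)
  q3 <- committors(transitionMatrix(rw), stationaryDist(rw), 1, 3)
  expect_equal(q3$qPlus, c(0, 0.5, 1))
})

test_that("committors match the closed-form birth-death formula", {
  for (seed in c(25, 26, 27)) {
    rw <- toyReversibleChain("birth-death", 5, seed = seed)
    p <- transitionMatrix(rw)
    q <- committors(p, stationaryDist(rw), 1, 5)
    expect_lt(max(abs(q$qPlus - bdCommittor(p))), 1e-10)
    # reversibility: backward committor is the complement
    expect_lt(max(abs(q$qMinus - (1 - q$qPlus))), 1e-10)
  }
})

test_that("birth-death stationary distribution matches hand computation", {
  rw <- toyReversibleChain("birth-death", 5, seed = 28)
  w <- affinityMatrix(rw)
  d <- rowSums(w)
  expect_equal(stationaryDist(rw), d / sum(d))
  expect_lt(max(abs(stationaryDist(rw) %*% transitionMatrix(rw) -
                    stationaryDist(rw))), 1e-12)
})

test_that("effective current conserves flux and is antisymmetric-positive", {
  for (seed in c(29, 30)) {
    rw <- toyReversibleChain("random", 6, seed = seed)
    phat <- optimalPhat(rep(1:3, 2), transitionMatrix(rw), stationaryDist(rw))
    muHat <- drop(crossprod(transcell:::.indicator(rep(1:3, 2), 3),
                            stationaryDist(rw)))
    q <- committors(phat, muHat, 1, 3)
    fp <- effectiveCurrent(phat, muHat, q$qPlus, q$qMinus)
    expect_true(all(fp >= 0))
    expect_true(all(fp * t(fp) == 0))
    expect_lt(abs(sum(fp[1, ]) - sum(fp[, 3])), 1e-10)
    # q+ non-decreasing along positive-current edges (acyclicity)
    pos <- which(fp > 0, arr.ind = TRUE)
    expect_true(all(q$qPlus[pos[, 2]] >= q$qPlus[pos[, 1]] - 1e-12))
  }
})

test_that("effective current matches a long-run Monte Carlo estimate", {
  rw <- toyReversibleChain("random", 4, seed = 31)
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  q <- committors(p, mu, 1, 4)
  f <- (mu * q$qMinus) * p * rep(q$qPlus, each = 4)
  diag(f) <- 0
  nSteps <- 2e6L
  set.seed(31)
  counts <- transcell:::.simulate_reactive_counts(p, nSteps, 1L, 4L, 1L)
  est <- counts / nSteps
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    se <- sqrt(max(f[i, j], 1e-12) / nSteps)
    expect_lt(abs(est[i, j] - f[i, j]), max(5 * se, 2e-4))
  }
})

test_that("path enumeration handles single, symmetric and diamond graphs", {
  # single path
  f1 <- matrix(0, 3, 3)
  f1[1, 2] <- 0.3; f1[2, 3] <- 0.2
  p1 <- enumeratePathLikelihoods(f1, 1, 3)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$likelihood, 1)
  expect_equal(p1$capacity, 0.2)
  # two mirror-symmetric parallel channels
  f2 <- matrix(0, 4, 4)
  f2[1, 2] <- f2[1, 3] <- 0.4
  f2[2, 4] <- f2[3, 4] <- 0.4
  p2 <- enumeratePathLikelihoods(f2, 1, 4)
  expect_equal(p2$likelihood, c(0.5, 0.5))
  # diamond with asymmetric currents: bottlenecks 0.1 and 0.25
  f3 <- matrix(0, 4, 4)
  f3[1, 2] <- 0.1; f3[2, 4] <- 0.3
  f3[1, 3] <- 0.25; f3[3, 4] <- 0.4
  p3 <- enumeratePathLikelihoods(f3, 1, 4)
  expect_equal(p3$capacity, c(0.25, 0.1))
  expect_equal(p3$likelihood, c(0.25, 0.1) / 0.35)
  expect_identical(p3$states[[1]], c(1L, 3L, 4L))
  # likelihoods invariant to uniform rescaling of the current
  p3b <- enumeratePathLikelihoods(10 * f3, 1, 4)
  expect_equal(p3b$likelihood, p3$likelihood)
  # bottleneck mode extracts the same two edge-disjoint channels here
  p3c <- enumeratePathLikelihoods(f3, 1, 4, mode = "bottleneck")
  expect_equal(p3c$capacity, p3$capacity)
})

test_that("path likelihoods sum to one on full TPT decompositions", {
  for (seed in c(32, 33)) {
    rw <- toyReversibleChain("random", 10, seed = seed)
    labels <- rep(1:5, 2)
    phat <- optimalPhat(labels, transitionMatrix(rw), stationaryDist(rw))
    muHat <- drop(crossprod(transcell:::.indicator(labels, 5),
                            stationaryDist(rw)))
    q <- committors(phat, muHat, 1, 5)
    fp <- effectiveCurrent(phat, muHat, q$qPlus, q$qMinus)
    paths <- enumeratePathLikelihoods(fp, 1, 5)
    expect_equal(sum(paths$likelihood), 1)
    expect_true(all(diff(paths$likelihood) <= 1e-15))
  }
})

test_that("flow tree matches brute-force search over all spanning trees", {
  set.seed(34)
  rw <- toyReversibleChain("random", 10, seed = 34)
  labels <- rep(1:5, 2)
  phat <- optimalPhat(labels, transitionMatrix(rw), stationaryDist(rw))
  muHat <- drop(crossprod(transcell:::.indicator(labels, 5),
                          stationaryDist(rw)))
  flow <- muHat * phat + t(muHat * phat)
  diag(flow) <- 0
  trees <- allSpanningTrees(5)
  bestW <- max(vapply(trees, function(e) sum(flow[e]), numeric(1)))
  tree <- maxProbabilityFlowTree(phat, muHat, root = 1)
  gotW <- sum(tree@edgeWeight, na.rm = TRUE)
  expect_equal(gotW, bestW)
  expect_identical(tree@root, 1L)
  expect_identical(sum(is.na(tree@parent)), 1L)
})

test_that("degenerate flow trees are star- and edge-shaped as expected", {
  # K = 2: a single edge
  phat <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  tree <- maxProbabilityFlowTree(phat, c(2 / 3, 1 / 3), root = 1)
  expect_identical(tree@parent, c(NA_integer_, 1L))
  # star-shaped chain through a hub
  K <- 5
  ph <- matrix(0, K, K)
  ph[1, 2:K] <- 0.1
  diag(ph) <- c(0.6, rep(0, K - 1))
  ph[2:K, 1] <- 0.3
  for (i in 2:K) ph[i, i] <- 0.7
  mh <- rep(1 / K, K)
  tr <- maxProbabilityFlowTree(ph, mh, root = 2)
  expect_identical(tr@parent[1], 2L)
  expect_true(all(tr@parent[3:K] == 1L))
})

test_that("most probable path tree follows the highest-probability routes", {
  phat <- matrix(c(0.8, 0.15, 0.05,
                   0.1, 0.8, 0.1,
                   0.02, 0.08, 0.9), 3, 3, byrow = TRUE)
  tree <- mostProbablePathTree(phat, root = 1)
  expect_identical(tree@method, "mppt")
  expect_identical(tree@parent[2], 1L)
  # route 1->2->3 has probability 0.15*0.1 = 0.015 < direct 0.05
  expect_identical(tree@parent[3], 1L)
})
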