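test_that("soft induced walk matches the naive triple loop", {
  set.seed(14)
  rw <- toyReversibleChain("random", 5, seed = 14)
  mu <- stationaryDist(rw)
  phat <- optimalPhat(c(1L, 1L, 2L, 2L, 2L), transitionMatrix(rw), mu)
  rho <- randSimplex(5, 2)
  got <- inducedSoftWalk(rho, phat, mu)
  expect_lt(max(abs(got - bruteSoftWalk(rho, phat, mu))), 1e-12)
  expect_lt(max(abs(rowSums(got) - 1)), 1e-10)
})

test_that("indicator membership reduces the soft walk to the hard one", {
  for (seed in c(15, 16, 17)) {
    rw <- toyReversibleChain("random", 7, seed = seed)
    p <- transitionMatrix(rw)
    mu <- stationaryDist(rw)
    set.seed(seed)
    labels <- sample(1:3, 7, replace = TRUE)
    labels[1:3] <- 1:3
    phat <- optimalPhat(labels, p, mu)
    ind <- diag(3)[labels, ]
    expect_lt(max(abs(inducedSoftWalk(ind, phat, mu) -
                      inducedWalk(labels, phat, mu))), 1e-12)
  }
})

test_that("K = 1 soft walk degenerates to the equilibrium kernel", {
  rw <- toyReversibleChain("random", 6, seed = 18)
  mu <- stationaryDist(rw)
  got <- inducedSoftWalk(matrix(1, 6, 1), matrix(1, 1, 1), mu)
  expect_lt(max(abs(got - matrix(mu, 6, 6, byrow = TRUE))), 1e-12)
})

test_that("analytic membership gradient matches finite differences", {
  rw <- toyReversibleChain("random", 20, seed = 19)
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  set.seed(19)
  labels <- c(rep(1:3, 6), 1L, 2L)
  phat <- optimalPhat(labels, p, mu)
  S <- mu * p
  C <- sum((mu * p^2) %*% (1 / mu))
  og <- transcell:::.membershipObjGrad
  h <- 1e-6
  for (trial in 1:5) {
    R <- randSimplex(20, 3)
    g <- og(R, phat, mu, S, C)$grad
    for (probe in 1:4) {
      i <- sample(20, 1); k <- sample(3, 1)
      Rp <- R; Rp[i, k] <- Rp[i, k] + h
      Rm <- R; Rm[i, k] <- Rm[i, k] - h
      fd <- (og(Rp, phat, mu, S, C, gradient = FALSE)$E -
             og(Rm, phat, mu, S, C, gradient = FALSE)$E) / (2 * h)
      expect_lt(abs(fd - g[i, k]) / max(abs(fd), 1e-8), 1e-5)
    }
  }
})

test_that("membership optimization descends and stays near an exact optimum", {
  # exactly lumpable chain: the indicator is a global optimum with E = 0
  rw <- toyReversibleChain("block", 12, seed = 20, nBlocks = 2L)
  labels <- attr(rw, "blockLabels")
  co <- coarseObjective(labels, transitionMatrix(rw), stationaryDist(rw))
  cg <- methods::new("CoarseGrainedModel", labels = labels, phat = co$phat,
                     muHat = co$muHat, objective = co$J, trace = co$J)
  mm <- optimizeMembership(cg, rw)
  expect_lt(mm@objective, 1e-6)
  expect_gt(min(mm@rho[cbind(1:12, labels)]), 0.9)
})

test_that("optimized membership never exceeds its initial objective", {
  for (seed in c(21, 22)) {
    rw <- toyReversibleChain("random", 25, seed = seed)
    cg <- optimizePartition(rw, 3, seed = 1)
    p <- transitionMatrix(rw); mu <- stationaryDist(rw)
    S <- mu * p
    C <- sum((mu * p^2) %*% (1 / mu))
    ind <- transcell:::.indicator(cg@labels, 3) * 0.99 + 0.005
    Einit <- transcell:::.membershipObjGrad(ind, cg@phat, mu, S, C,
                                            gradient = FALSE)$E
    mm <- optimizeMembership(cg, rw)
    expect_lte(mm@objective, Einit + 1e-9)
    expect_true(methods::validObject(mm))
  }
})

test_that("a mirror-symmetric midpoint cell receives an even membership", {
  # two reflected blobs plus one cell exactly on the symmetry plane;
  # symmetry forces rho = (0.5, 0.5) at the midpoint
  set.seed(23)
  half <- matrix(rnorm(60, 0, 0.4), 30, 2) + cbind(rep(2, 30), 0)
  coords <- rbind(half, -half, c(0, 0))
  w <- buildAffinity(coords, 8)
  w <- (w + w[c(31:60, 1:30, 61), c(31:60, 1:30, 61)]) / 2  # exact symmetry
  rw <- buildRandomWalk(w)
  cg <- optimizePartition(rw, 2, seed = 1)
  mm <- optimizeMembership(cg, rw)
  expect_lt(abs(mm@rho[61, 1] - 0.5), 0.05)
})

test_that("transition entropy respects its formula and bounds", {
  expect_equal(membershipEntropy(matrix(c(1, 0, 0), 1, 3)), 0)
  expect_equal(membershipEntropy(matrix(0.25, 1, 4)), log(4))
  set.seed(24)
  rho <- randSimplex(50, 4)
  H <- membershipEntropy(rho)
  expect_true(all(H >= 0 & H <= log(4)))
  expect_equal(H, -rowSums(rho * log(rho)))
})
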