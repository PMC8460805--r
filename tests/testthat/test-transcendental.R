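test_that("transition cell score follows its defining ratio", {
  rho <- rbind(c(0.3, 0.1, 0.6),
               c(1, 0, 0),
               c(0, 1, 0),
               c(0.45, 0.45, 0.1),
               c(0.25, 0.65, 0.1),
               c(0.5, 0.4, 0.1),
               c(0.85, 0.05, 0.1),
               c(0.05, 0.85, 0.1),
               c(0.6, 0.3, 0.1),
               c(0.2, 0.7, 0.1),
               c(0.75, 0.15, 0.1),
               c(0.35, 0.55, 0.1))
  ta <- transitionCellScore(rho, 1, 2, relevanceThreshold = 0.4)
  expect_equal(unname(ta@tau[ta@cells == 1]), 0.75)
  expect_equal(unname(ta@tau[ta@cells == 2]), 1)
  expect_equal(unname(ta@tau[ta@cells == 3]), 0)
  # ordering is by descending tau
  expect_true(all(diff(ta@tau) <= 0))
  # antisymmetry: tau_ij + tau_ji = 1 cell by cell
  tb <- transitionCellScore(rho, 2, 1, relevanceThreshold = 0.4)
  expect_equal(sort(ta@cells), sort(tb@cells))
  expect_equal(ta@tau[order(ta@cells)] + tb@tau[order(tb@cells)],
               rep(1, length(ta@tau)))
})

test_that("relevance threshold filters cells and can empty the set", {
  rho <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.1, 0.8), c(0.5, 0.45, 0.05))
  ta <- transitionCellScore(rho, 1, 2, relevanceThreshold = 0.8)
  expect_identical(sort(ta@cells), c(1L, 3L))
  expect_error(transitionCellScore(rho, 2, 3, relevanceThreshold = 0.99),
               "relevanceThreshold")
})

test_that("logistic layer fit recovers generating parameters", {
  r <- 1:100
  tau <- 1 / (1 + exp((r - 50) / 5))
  fit <- fitTransitionLayer(tau)
  expect_lt(abs(fit$params[["r0"]] - 50) / 50, 0.01)
  expect_lt(abs(fit$params[["s"]] - 5) / 5, 0.01)
})

test_that("step and ramp score sequences give the expected layer sizes", {
  step <- c(rep(1, 50), rep(0, 50))
  fitS <- suppressWarnings(fitTransitionLayer(step))
  expect_identical(sum(fitS$mask), 0L)
  ramp <- seq(1, 0, length.out = 100)
  fitR <- fitTransitionLayer(ramp)
  expect_identical(sum(fitR$mask), 80L)
})

test_that("gene classes are assigned per their definitions", {
  # 30 relevant cells: 10 stable side i (tau ~ 1), 10 transition, 10 side j
  n <- 30
  tau <- c(seq(1, 0.95, length.out = 10), seq(0.85, 0.15, length.out = 10),
           seq(0.05, 0, length.out = 10))
  rho <- cbind(tau, 1 - tau)
  ta <- transitionCellScore(rho, 1, 2, relevanceThreshold = 0)
  expect_identical(sum(ta@transitionMask), 10L)
  ord <- ta@cells  # descending tau = construction order
  set.seed(41)
  g_td <- tau + 0.05 + rnorm(n, 0, 1e-3)   # tracks the score
  g_msdown <- c(rep(5, 10), rep(0, 20)) + abs(rnorm(n, 0, 0.05))
  g_msup <- c(rep(0, 20), rep(5, 10)) + abs(rnorm(n, 0, 0.05))
  g_ihup <- c(rep(0, 10), rep(5, 20)) + abs(rnorm(n, 0, 0.05))
  g_ihdown <- c(rep(5, 20), rep(0, 10)) + abs(rnorm(n, 0, 0.05))
  g_flat <- abs(rnorm(n, 1, 0.05))
  expr <- expressionMatrix(
    cbind(TDg = g_td[order(ord)], MSdown = g_msdown[order(ord)],
          MSup = g_msup[order(ord)], IHup = g_ihup[order(ord)],
          IHdown = g_ihdown[order(ord)], FLAT = g_flat[order(ord)]))
  gc <- classifyGenes(expr, ta, tdCorThreshold = 0.5, fdr = 0.05)
  lab <- setNames(gc@table$label, gc@table$gene)
  expect_identical(unname(lab["TDg"]), "TD")
  expect_identical(unname(lab["MSdown"]), "MS-down")
  expect_identical(unname(lab["MSup"]), "MS-up")
  expect_identical(unname(lab["IHup"]), "IH-up")
  expect_identical(unname(lab["IHdown"]), "IH-down")
  expect_false("FLAT" %in% names(lab))
})

test_that("gene order does not affect classification", {
  n <- 30
  tau <- c(seq(1, 0.95, length.out = 10), seq(0.85, 0.15, length.out = 10),
           seq(0.05, 0, length.out = 10))
  rho <- cbind(tau, 1 - tau)
  ta <- transitionCellScore(rho, 1, 2, relevanceThreshold = 0)
  set.seed(42)
  vals <- matrix(abs(rnorm(n * 8)), n, 8)
  vals[, 3] <- tau[order(ta@cells)] + 5
  colnames(vals) <- paste0("g", 1:8)
  e1 <- expressionMatrix(vals)
  perm <- sample(8)
  e2 <- expressionMatrix(vals[, perm])
  t1 <- classifyGenes(e1, ta)@table
  t2 <- classifyGenes(e2, ta)@table
  t2 <- t2[match(t1$gene, t2$gene), ]
  expect_identical(t1$label, t2$label)
  expect_equal(t1$statistic, t2$statistic)
})

test_that("a gene equal to the score is a perfect transition driver", {
  tau <- seq(0.98, 0.02, length.out = 40)
  rho <- cbind(tau, 1 - tau)
  ta <- transitionCellScore(rho, 1, 2, relevanceThreshold = 0)
  expr <- expressionMatrix(matrix(tau[order(ta@cells)], ncol = 1,
                                  dimnames = list(NULL, "driver")))
  gc <- classifyGenes(expr, ta)
  expect_identical(gc@table$label, "TD")
  expect_equal(gc@table$statistic, 1)
})
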