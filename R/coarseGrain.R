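#' Mu-weighted squared Hilbert-Schmidt distance between transition matrices
#'
#' ||A - B||^2_mu = sum_{x,y} mu(x)/mu(y) (A - B)(x,y)^2, the natural norm
#' for comparing reversible transition matrices sharing the stationary
#' distribution mu.
#'
#' @param a,b N x N matrices
#' @param mu strictly positive stationary distribution
#' @return nonnegative scalar
#' @export
hsDistance <- function(a, b, mu) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch between a and b")
  if (any(mu <= 0)) stop("mu must be strictly positive")
  d <- a - b
  sum((mu * d^2) %*% (1 / mu))
}

.indicator <- function(labels, K) {
  n <- length(labels)
  ind <- matrix(0, n, K)
  ind[cbind(seq_len(n), labels)] <- 1
  ind
}

#' Cell-cell walk induced by a coarse-grained model
#'
#' phat(x,y) = sum_{i,j} 1_{S_i}(x) Phat_ij 1_{S_j}(y) mu(y)/muhat_j: a jump
#' from x in S_i first switches basin with probability Phat_ij, then lands
#' on a particular y in S_j according to y's share mu(y)/muhat_j of the
#' basin's equilibrium mass.
#'
#' @param labels partition of cells into 1..K
#' @param phat K x K row-stochastic coarse transition matrix
#' @param mu strictly positive cell stationary distribution
#' @return row-stochastic N x N matrix
#' @export
inducedWalk <- function(labels, phat, mu) {
  K <- nrow(phat)
  if (any(tabulate(labels, K) == 0L)) stop("empty cluster in partition")
  if (any(mu <= 0)) stop("mu must be strictly positive")
  muHat <- as.vector(tapply(mu, factor(labels, levels = seq_len(K)), sum))
  # rows pick the block row of phat, columns weight by mu(y)/muhat_j
  phat[labels, labels, drop = FALSE] * rep(mu / muHat[labels], each = length(labels))
}

#' Flux and stationary mass of a partition
#'
#' F_ij = sum_{x in S_i, y in S_j} mu(x) p(x,y), muhat_i = sum_{x in S_i} mu(x).
#' @noRd
.blockFlux <- function(labels, p, mu, K) {
  ind <- .indicator(labels, K)
  flux <- crossprod(ind, (mu * p) %*% ind)
  muHat <- drop(crossprod(ind, mu))
  list(flux = flux, muHat = muHat)
}

#' Optimal coarse transition matrix for a fixed partition
#'
#' For fixed basins the objective J is quadratic in Phat and its minimizer
#' is the mu-weighted aggregation Phat_ij = F_ij / muhat_i with F the
#' stationary block flux; the row-sum and nonnegativity constraints are
#' satisfied automatically at this minimizer.
#'
#' @param labels partition of cells into 1..K
#' @param p cell-cell transition matrix
#' @param mu cell stationary distribution
#' @param K number of clusters (defaults to max(labels))
#' @return K x K row-stochastic matrix
#' @export
optimalPhat <- function(labels, p, mu, K = max(labels)) {
  if (any(tabulate(labels, K) == 0L)) stop("empty cluster in partition")
  bf <- .blockFlux(labels, p, mu, K)
  unname(as.matrix(bf$flux / bf$muHat))
}

#' Coarse-graining objective for a partition (with optimal Phat)
#'
#' Evaluates J = ||phat_induced - p||^2_mu at the optimal Phat through the
#' block-aggregated identity J = C - sum_ij F_ij^2/(muhat_i muhat_j), where
#' C = sum mu(x)/mu(y) p(x,y)^2; no dense induced walk is materialized.
#'
#' @param labels partition
#' @param p,mu cell walk and stationary distribution
#' @param K number of clusters
#' @param constant optionally precomputed C
#' @return list with `J`, `phat`, `muHat`, `flux`
#' @export
coarseObjective <- function(labels, p, mu, K = max(labels), constant = NULL) {
  if (is.null(constant)) constant <- sum((mu * p^2) %*% (1 / mu))
  bf <- .blockFlux(labels, p, mu, K)
  V <- sum(bf$flux^2 / tcrossprod(bf$muHat))
  list(J = constant - V, phat = unname(as.matrix(bf$flux / bf$muHat)),
       muHat = bf$muHat, flux = unname(as.matrix(bf$flux)))
}

# Sweep-cut initialization for K = 2: evaluate J for every threshold cut
# along the ordering of the slowest nontrivial eigenvector (the classic
# spectral sweep) with O(N) incremental flux updates, and return the best
# cut's labels.
.sweepCutLabels <- function(p, mu, v2) {
  n <- length(mu)
  o <- order(v2)
  lab <- rep(2L, n)
  F <- matrix(0, 2, 2)
  F[2, 2] <- sum(mu * p)
  muHat <- c(0, sum(mu))
  bestV <- -Inf
  bestCut <- 0L
  for (idx in seq_len(n - 1L)) {
    x <- o[idx]
    px <- mu[x] * p[x, ]
    py <- mu * p[, x]
    s <- px[x]
    px[x] <- 0; py[x] <- 0
    in1 <- lab == 1L
    u <- c(sum(px[in1]), sum(px[!in1]))
    v <- c(sum(py[in1]), sum(py[!in1]))
    F[2, ] <- F[2, ] - u; F[1, ] <- F[1, ] + u
    F[, 2] <- F[, 2] - v; F[, 1] <- F[, 1] + v
    F[2, 2] <- F[2, 2] - s; F[1, 1] <- F[1, 1] + s
    muHat <- muHat + c(mu[x], -mu[x])
    lab[x] <- 1L
    V <- sum(F^2 / tcrossprod(muHat))
    if (V > bestV) { bestV <- V; bestCut <- idx }
  }
  lab <- rep(2L, n)
  lab[o[seq_len(bestCut)]] <- 1L
  lab
}

#' Learn the attractor partition and coarse transition matrix
#'
#' Minimizes J[S_k, Phat] = ||phat_induced - p||^2_mu by alternating
#' (i) k-means initialization on the top-K right eigenvectors of p scaled by
#' their eigenvalues, (ii) the closed-form optimal Phat, and (iii) greedy
#' single-cell reassignment passes that accept only strictly J-decreasing
#' moves (ties between target clusters broken by lowest index, cells visited
#' in index order). The best of `nRestarts` seeded starts is kept, ties
#' broken by lowest restart index. J is non-increasing along the recorded
#' trace.
#'
#' @param rw a [CellRandomWalk-class] (or any object with a transition
#'   matrix and stationary distribution)
#' @param K number of attractors, 2 <= K < N
#' @param seed integer seed for the restarts
#' @param nRestarts number of seeded k-means starts
#' @param maxIter cap on greedy passes per restart
#' @return a [CoarseGrainedModel-class]
#' @export
optimizePartition <- function(rw, K, seed = 1L, nRestarts = 10L, maxIter = 100L) {
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  n <- nrow(p)
  if (K < 2 || K >= n) stop("need 2 <= K < N")
  constant <- sum((mu * p^2) %*% (1 / mu))
  sp <- walkSpectrum(rw, k = K)
  emb <- sp$vectors %*% diag(sp$values, K)
  # on small chains the eigenvector k-means starts can all fall into one
  # basin of the greedy scheme; random-label restarts diversify the search
  nRandom <- if (n <= 200L) nRestarts else 0L
  nSweep <- if (K == 2L) 1L else 0L
  best <- NULL
  for (r in seq_len(nRestarts + nRandom + nSweep)) {
    set.seed(seed + r - 1L)
    if (r <= nRestarts) {
      km <- tryCatch(stats::kmeans(emb, centers = K, nstart = 1L,
                                   iter.max = 50L),
                     error = function(e) NULL)
      if (is.null(km)) next
      labels0 <- km$cluster
    } else if (r <= nRestarts + nRandom) {
      labels0 <- c(seq_len(K), sample(seq_len(K), n - K, replace = TRUE))
    } else {
      # spectral sweep cut along the slowest nontrivial eigenvector
      labels0 <- .sweepCutLabels(p, mu, sp$vectors[, 2])
    }
    if (any(tabulate(labels0, K) == 0L)) next
    ref <- .refine_partition(p, mu, as.integer(labels0), as.integer(K),
                             as.integer(maxIter), 1e-10)
    J <- constant - ref$vtrace[length(ref$vtrace)]
    if (is.null(best) || J < best$J - 1e-14) {
      best <- list(J = J, labels = ref$labels,
                   trace = constant - ref$vtrace)
    }
  }
  if (is.null(best)) stop("partition optimization failed to produce K nonempty clusters")
  # relabel clusters by order of first occurrence for determinism
  labels <- match(best$labels, unique(best$labels))
  co <- coarseObjective(labels, p, mu, K, constant)
  methods::new("CoarseGrainedModel", labels = as.integer(labels),
               phat = co$phat, muHat = co$muHat, objective = co$J,
               trace = best$trace)
}
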