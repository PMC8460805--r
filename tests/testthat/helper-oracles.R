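# Independent brute-force oracles used across the suite.

# O(N^2) double-loop evaluation of the locally-scaled Gaussian kernel on the
# union-kNN graph; mirrors the definition, not the implementation.
bruteAffinity <- function(coords, k, mode = "local-adaptive") {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  sigma <- numeric(n)
  nbr <- vector("list", n)
  for (x in seq_len(n)) {
    o <- order(d[x, ])
    nbr[[x]] <- o[2:(k + 1)]
    sigma[x] <- d[x, o[k + 1]]
  }
  if (mode == "global") sigma <- rep(median(sigma), n)
  w <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    if (y %in% nbr[[x]] || x %in% nbr[[y]])
      w[x, y] <- exp(-d[x, y]^2 / (sigma[x] * sigma[y]))
  }
  w
}

# naive triple-loop evaluation of the membership-induced walk
bruteSoftWalk <- function(rho, phat, mu) {
  n <- nrow(rho); K <- ncol(rho)
  muT <- colSums(rho * mu)
  p <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n))
    for (i in seq_len(K)) for (j in seq_len(K))
      p[x, y] <- p[x, y] + rho[x, i] * phat[i, j] * rho[y, j] * mu[y] / muT[j]
  p
}

# naive double-loop mu-weighted squared Hilbert-Schmidt distance
bruteHs <- function(a, b, mu) {
  s <- 0
  for (x in seq_len(nrow(a))) for (y in seq_len(ncol(a)))
    s <- s + mu[x] / mu[y] * (a[x, y] - b[x, y])^2
  s
}

# closed-form forward committor of a birth-death chain for A = {1}, B = {n}
bdCommittor <- function(p) {
  n <- nrow(p)
  rho <- numeric(n - 1)  # rho_l = prod_{m=2}^{l+1} q_m / p_m over interior
  ratio <- 1
  rho[1] <- 1
  for (l in 2:(n - 1)) {
    ratio <- ratio * p[l, l - 1] / p[l, l + 1]
    rho[l] <- ratio
  }
  q <- numeric(n)
  for (j in 2:(n - 1)) q[j] <- sum(rho[1:(j - 1)]) / sum(rho)
  q[n] <- 1
  q
}

# all labeled spanning trees on K vertices via Pruefer sequences
allSpanningTrees <- function(K) {
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), K - 2)))
  lapply(seq_len(nrow(seqs)), function(r) {
    prf <- seqs[r, ]
    degree <- rep(1L, K)
    for (v in prf) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, K - 1, 2)
    avail <- rep(TRUE, K)
    for (i in seq_along(prf)) {
      leaf <- min(which(degree == 1L & avail))
      edges[i, ] <- c(leaf, prf[i])
      avail[leaf] <- FALSE
      degree[prf[i]] <- degree[prf[i]] - 1L
      degree[leaf] <- 0L
    }
    rest <- which(avail)
    edges[K - 1, ] <- rest
    edges
  })
}

# random row-simplex matrix
randSimplex <- function(n, K) {
  m <- matrix(rexp(n * K), n, K)
  m / rowSums(m)
}

# small two-blob coordinate fixture
twoBlobs <- function(n = 40, sep = 3, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(n, 0, 0.5), n / 2, 2),
        matrix(rnorm(n, sep, 0.5), n / 2, 2))
}
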