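#' Build a locally-scaled Gaussian affinity on the kNN graph
#'
#' Affinity w(x,y) = exp(-||x-y||^2 / (sigma_x sigma_y)) on the symmetrized
#' (union) k-nearest-neighbour graph and 0 elsewhere, with w(x,x) = 0.
#' In "local-adaptive" mode sigma_x is the distance from x to its k-th
#' neighbour; in "global" mode every sigma is the median of those distances.
#' The symmetric kernel guarantees the induced random walk is reversible.
#'
#' @param coords N x d coordinate matrix
#' @param kNeighbors number of neighbours (2 <= k < N)
#' @param bandwidthMode "local-adaptive" or "global"
#' @param selfLoops add w(x,x) = 1 self-affinities instead of 0
#' @param densityNormalize divide the kernel by the square root of the
#'   sampling-density estimate at both ends (anisotropic-diffusion
#'   normalization). With a global bandwidth this makes the continuum limit
#'   of the induced walk the overdamped Langevin diffusion whose equilibrium
#'   is the sampling density, so coarse-grained transition probabilities
#'   inherit the Arrhenius/Kramers dependence on the barrier height.
#' @return symmetric nonnegative N x N affinity matrix
#' @export
buildAffinity <- function(coords, kNeighbors,
                          bandwidthMode = c("local-adaptive", "global"),
                          selfLoops = FALSE, densityNormalize = FALSE) {
  bandwidthMode <- match.arg(bandwidthMode)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (kNeighbors < 2 || kNeighbors >= n)
    stop("need 2 <= kNeighbors < N (got k = ", kNeighbors, ", N = ", n, ")")
  d2 <- as.matrix(stats::dist(coords))^2
  # distance to the k-th neighbour (excluding self)
  kd2 <- apply(d2, 1, function(r) sort(r)[kNeighbors + 1L])
  sigma <- sqrt(kd2)
  eps <- sqrt(.Machine$double.eps)
  if (any(sigma < eps)) {
    warning("duplicate points collapse the local bandwidth; flooring sigma")
    sigma <- pmax(sigma, eps)
  }
  if (bandwidthMode == "global") sigma <- rep(stats::median(sigma), n)
  # union-kNN adjacency
  adj <- matrix(FALSE, n, n)
  for (x in seq_len(n)) {
    nb <- order(d2[x, ])[2:(kNeighbors + 1L)]
    adj[x, nb] <- TRUE
  }
  adj <- adj | t(adj)
  w <- exp(-d2 / tcrossprod(sigma))
  w[!adj] <- 0
  diag(w) <- if (selfLoops) 1 else 0
  w <- (w + t(w)) / 2  # remove numerically tiny asymmetries
  if (densityNormalize) {
    q <- rowSums(w)  # kernel density estimate up to a constant
    q <- pmax(q, .Machine$double.eps)
    w <- w / sqrt(tcrossprod(q))
  }
  w
}

#' Build the reversible cellular random walk from an affinity
#'
#' p(x,y) = w(x,y)/d(x) with d(x) = sum_z w(x,z) and stationary distribution
#' mu(x) = d(x)/sum_z d(z); detailed balance mu(x)p(x,y) = mu(y)p(y,x) holds
#' by construction because w is symmetric.
#'
#' @param w symmetric nonnegative affinity matrix
#' @return a [CellRandomWalk-class]
#' @export
buildRandomWalk <- function(w) {
  w <- as.matrix(w)
  if (max(abs(w - t(w))) > 1e-10) stop("affinity must be symmetric")
  if (min(w) < 0) stop("affinity must be nonnegative")
  d <- rowSums(w)
  if (any(d == 0)) {
    bad <- which(d == 0)
    stop("isolated cells with zero affinity: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  if (igraph::components(g)$no > 1)
    stop("affinity graph is disconnected; increase kNeighbors")
  p <- w / d
  mu <- d / sum(d)
  methods::new("CellRandomWalk", affinity = w, prob = p, degree = d, mu = mu)
}

#' Leading eigenvalues and eigenvectors of a reversible walk
#'
#' Detailed balance makes D^{1/2} p D^{-1/2} symmetric (D = diag of the
#' degrees), so the spectrum is real in [-1, 1]. Right eigenvectors of p are
#' recovered as D^{-1/2} times the symmetric eigenvectors, and signs are
#' fixed so the largest-magnitude entry of each vector is positive.
#'
#' @param rw a [CellRandomWalk-class]
#' @param k number of leading eigenpairs
#' @return list with `values` (descending) and `vectors` (right eigenvectors
#'   of p, one column per eigenvalue)
#' @export
walkSpectrum <- function(rw, k = nrow(rw@prob)) {
  d <- rw@degree
  s <- sqrt(d)
  sym <- rw@affinity / tcrossprod(s)
  e <- eigen(sym, symmetric = TRUE)
  k <- min(k, length(e$values))
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE] / s
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs)
}

#' Eigen-peak index over candidate attractor numbers
#'
#' Spectral diagnostic for choosing K: the index for a candidate K is the
#' normalized eigen-gap (lambda_K - lambda_{K+1}) / (1 - lambda_{K+1});
#' peaks mark numbers of metastable attractors at different resolutions, and
#' "auto" selection takes the argmax over 2..kmax. The raw spectrum is kept
#' so K can also be chosen by inspection or prior knowledge.
#'
#' @param rw a [CellRandomWalk-class]
#' @param kmax largest candidate K (kmax < N)
#' @return an [EigenPeakCurve-class]
#' @export
eigenPeakIndex <- function(rw, kmax = 8L) {
  n <- nrow(rw@prob)
  if (kmax >= n) stop("kmax must be smaller than the number of cells")
  sp <- walkSpectrum(rw, k = kmax + 1L)
  lam <- sp$values
  ks <- 2:kmax
  gap <- lam[ks] - lam[ks + 1L]
  denom <- pmax(1 - lam[ks + 1L], 1e-12)
  epi <- gap / denom
  names(epi) <- ks
  methods::new("EigenPeakCurve", eigenvalues = lam, epi = epi,
               bestK = as.integer(ks[which.max(epi)]))
}
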