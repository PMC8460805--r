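#' Attractor centers in the 2-D embedding
#'
#' Y_k is the mean 2-D position of the cells confidently inside basin k
#' (membership rho_k >= coreThreshold); when fewer than 5 cells pass, the 10
#' cells with highest rho_k are used instead so small basins still get a
#' center.
#'
#' @param coords2d N x 2 embedding (user-provided or first two PCs)
#' @param rho N x K membership matrix
#' @param coreThreshold membership cutoff defining basin cores (0.5, 1)
#' @return K x 2 matrix of centers
#' @export
attractorCenters <- function(coords2d, rho, coreThreshold = 0.9) {
  stopifnot(coreThreshold > 0.5, coreThreshold < 1)
  coords2d <- as.matrix(coords2d)
  K <- ncol(rho)
  centers <- matrix(NA_real_, K, 2)
  for (k in seq_len(K)) {
    idx <- which(rho[, k] >= coreThreshold)
    if (length(idx) < 5L)
      idx <- order(rho[, k], decreasing = TRUE)[seq_len(min(10L, nrow(rho)))]
    if (!length(idx)) stop("attractor ", k, " has no cells")
    centers[k, ] <- colMeans(coords2d[idx, , drop = FALSE])
  }
  centers
}

#' Membership-weighted transition coordinates
#'
#' xi(x) = sum_k rho_k(x) Y_k: each cell sits at the convex combination of
#' the attractor centers weighted by its membership, so a cell with mixed
#' identity between basins i and j lies between Y_i and Y_j.
#'
#' @param rho N x K membership matrix
#' @param centers K x 2 attractor centers
#' @return N x 2 matrix of coordinates
#' @export
transitionCoordinates <- function(rho, centers) {
  if (any(!is.finite(centers))) stop("centers must be finite")
  rho %*% centers
}

#' Fit the cell-fate dynamical manifold
#'
#' Approximates the stationary density of the coarse dynamics by the
#' Gaussian mixture p(z) = sum_k muHat_k N(z; Y_k, Lambda_k), where
#' Lambda_k is the rho_k-weighted covariance of the 2-D coordinates about
#' Y_k with eigenvalues floored at 1e-3 times the squared data span (so the
#' landscape stays finite). The landscape is phi(z) = -log p(z), evaluated
#' per cell at its transition coordinate; deeper basins correspond to larger
#' stationary mass.
#'
#' @param coords2d N x 2 embedding
#' @param rho N x K membership matrix
#' @param muHat coarse stationary distribution (mixture weights)
#' @param coreThreshold passed to [attractorCenters()]
#' @return a [DynamicalManifold-class]
#' @export
fitLandscape <- function(coords2d, rho, muHat, coreThreshold = 0.9) {
  coords2d <- as.matrix(coords2d)
  K <- ncol(rho)
  centers <- attractorCenters(coords2d, rho, coreThreshold)
  span <- max(apply(coords2d, 2, function(z) diff(range(z))))
  floorEv <- 1e-3 * span^2
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    wk <- rho[, k] / sum(rho[, k])
    d <- sweep(coords2d, 2, centers[k, ])
    S <- crossprod(d * wk, d)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ev <- pmax(e$values, floorEv)
    covs[[k]] <- e$vectors %*% (ev * t(e$vectors))
  }
  xi <- transitionCoordinates(rho, centers)
  energy <- landscapeEnergy(xi, centers, covs, muHat)
  methods::new("DynamicalManifold", centers = centers, covariances = covs,
               weights = muHat / sum(muHat), xi = xi, energy = energy)
}

#' Evaluate the landscape phi(z) = -log p(z)
#'
#' @param z M x 2 matrix of evaluation points
#' @param centers,covariances,weights mixture parameters, or pass a
#'   [DynamicalManifold-class] as `centers`
#' @return length-M vector of energies
#' @export
landscapeEnergy <- function(z, centers, covariances = NULL, weights = NULL) {
  if (methods::is(centers, "DynamicalManifold")) {
    m <- centers
    centers <- m@centers; covariances <- m@covariances; weights <- m@weights
  }
  z <- matrix(as.numeric(z), ncol = 2)
  dens <- numeric(nrow(z))
  for (k in seq_len(nrow(centers))) {
    S <- covariances[[k]]
    Sinv <- solve(S)
    detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    d <- sweep(z, 2, centers[k, ])
    qf <- rowSums((d %*% Sinv) * d)
    dens <- dens + weights[k] * exp(-qf / 2) / (2 * pi * sqrt(detS))
  }
  -log(dens)
}

#' Landscape on a regular plotting grid
#'
#' @param manifold a [DynamicalManifold-class]
#' @param n grid resolution per axis
#' @param pad fractional padding around the cell coordinates
#' @return data.frame with columns `z1`, `z2`, `energy`
#' @export
landscapeGrid <- function(manifold, n = 80L, pad = 0.15) {
  r1 <- range(manifold@xi[, 1]); r2 <- range(manifold@xi[, 2])
  e1 <- diff(r1) * pad + 1e-9; e2 <- diff(r2) * pad + 1e-9
  g1 <- seq(r1[1] - e1, r1[2] + e1, length.out = n)
  g2 <- seq(r2[1] - e2, r2[2] + e2, length.out = n)
  gr <- expand.grid(z1 = g1, z2 = g2)
  gr$energy <- landscapeEnergy(as.matrix(gr), manifold@centers,
                               manifold@covariances, manifold@weights)
  gr
}

#' Construct the dynamical manifold for a fitted model
#'
#' @param model a [CellFateModel-class]
#' @param coords2d optional N x 2 embedding overriding the model's stored
#'   2-D coordinates
#' @param coreThreshold passed to [attractorCenters()]
#' @return a [DynamicalManifold-class]
#' @export
dynamicalManifold <- function(model, coords2d = NULL, coreThreshold = 0.9) {
  if (is.null(coords2d)) coords2d <- model@coords2d
  rho <- membershipMatrix(model)
  if (nrow(as.matrix(coords2d)) != nrow(rho))
    stop("coords2d must have one row per cell")
  fitLandscape(coords2d, rho, model@coarse@muHat, coreThreshold)
}
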