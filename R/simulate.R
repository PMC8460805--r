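#' Construct an SDE model
#'
#' When a potential is supplied the drift must equal its negative gradient;
#' this is checked at construction by central finite differences at a few
#' probe points.
#'
#' @param drift function f(x, t) returning the drift vector
#' @param noise function sigma(x, t) returning the (scalar or per-coordinate)
#'   noise amplitude
#' @param dim state dimension
#' @param potential optional potential U(x)
#' @param minima,saddles,maxima known critical points (rows), optional
#' @param barrier energy difference between a minimum and the adjacent
#'   first-order saddle, if known
#' @return an [SDEModel-class]
#' @export
sdeModel <- function(drift, noise, dim, potential = NULL,
                     minima = matrix(numeric(0), 0, dim),
                     saddles = matrix(numeric(0), 0, dim),
                     maxima = matrix(numeric(0), 0, dim),
                     barrier = NA_real_) {
  dim <- as.integer(dim)
  if (!is.null(potential)) {
    h <- 1e-5
    probes <- rbind(rep(0.1, dim), rep(-0.3, dim), seq_len(dim) / (dim + 1))
    for (r in seq_len(nrow(probes))) {
      x <- probes[r, ]
      g <- vapply(seq_len(dim), function(i) {
        e <- numeric(dim); e[i] <- h
        (potential(x + e) - potential(x - e)) / (2 * h)
      }, numeric(1))
      if (max(abs(drift(x, 0) + g)) > 1e-6)
        stop("drift is not -grad(potential) at probe point ", r)
    }
  }
  methods::new("SDEModel", drift = drift, noise = noise, dim = dim,
               potential = potential, minima = as.matrix(minima),
               saddles = as.matrix(saddles), maxima = as.matrix(maxima),
               barrier = barrier)
}

#' Euler-Maruyama integration of an SDE model
#'
#' x_{t+1} = x_t + f(x_t, t) dt + sigma(x_t, t) sqrt(dt) xi_t with standard
#' normal draws from the seeded stream; bit-reproducible given the seed.
#'
#' @param model an [SDEModel-class]
#' @param x0 initial state
#' @param dt time step (> 0)
#' @param nSteps number of steps (>= 1)
#' @param seed integer seed
#' @return (nSteps + 1) x dim matrix of states, attribute "time" holding the
#'   time stamps
#' @export
eulerMaruyama <- function(model, x0, dt, nSteps, seed = 1L) {
  stopifnot(dt > 0, nSteps >= 1)
  set.seed(seed)
  d <- model@dim
  out <- matrix(NA_real_, nSteps + 1L, d)
  out[1, ] <- x0
  noise <- matrix(stats::rnorm(nSteps * d), nSteps, d)
  sdt <- sqrt(dt)
  x <- as.numeric(x0)
  for (s in seq_len(nSteps)) {
    t <- (s - 1) * dt
    x <- x + model@drift(x, t) * dt + model@noise(x, t) * sdt * noise[s, ]
    if (any(!is.finite(x)))
      stop("non-finite state at step ", s, "; reduce dt")
    out[s + 1L, ] <- x
  }
  attr(out, "time") <- (0:nSteps) * dt
  out
}

# --- saddle-node (fold) bifurcation benchmark -------------------------------

# roots of s + x - x^3 = 0: stable upper/lower branches and the middle saddle
.cubicRoots <- function(s) {
  r <- polyroot(c(s, 1, 0, -1))  # s + x - x^3
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  r
}

#' Simulate the saddle-node transition benchmark
#'
#' One-dimensional overdamped dynamics dx = (s(t) + x - x^3) dt +
#' noise dW with the external signal s(t) ramping slowly downward through
#' the fold at s* = -2/(3 sqrt(3)), so the upper stable branch is
#' annihilated and the state drops to the lower branch; noise induces the
#' switch slightly before the deterministic fold. Snapshots are taken at
#' `nCells` equally spaced times along one trajectory. Ground truth per
#' sample: basin of the noiseless flow at the sample's signal value
#' (upper/lower branch = attractor 1/2), with region "core" when the state
#' is within `coreWidth` of its stable branch and "transition-layer"
#' otherwise.
#'
#' @param signalRate downward ramp speed of the signal per unit time
#' @param noise noise amplitude (0 recovers the deterministic fold)
#' @param nCells number of snapshot samples (>= 100)
#' @param seed integer seed
#' @param s0 initial signal value
#' @param sEnd final signal value, held fixed after the ramp (the settling
#'   phase adds 30 percent of the ramp time so the arriving branch is
#'   sampled regardless of when the switch happens)
#' @param dt integrator step
#' @param coreWidth distance to the stable branch defining core cells
#' @return a [SimulatedDataset-class] with 1-D coords
#' @export
simulateSaddleNode <- function(signalRate = 0.005, noise = 0.3,
                               nCells = 2000L, seed = 1L, s0 = 0.0,
                               sEnd = -0.5, dt = 1e-3, coreWidth = 0.35) {
  if (nCells < 100L) stop("nCells must be >= 100")
  Ttot <- 1.3 * (s0 - sEnd) / signalRate
  signal <- function(t) pmax(s0 - signalRate * t, sEnd)
  model <- sdeModel(
    drift = function(x, t) signal(t) + x - x^3,
    noise = function(x, t) noise,
    dim = 1L)
  nSteps <- ceiling(Ttot / dt)
  x0 <- max(.cubicRoots(s0))  # start on the upper branch
  traj <- eulerMaruyama(model, x0, dt, nSteps, seed = seed)
  tt <- attr(traj, "time")
  idx <- round(seq(1, nSteps + 1L, length.out = nCells))
  coords <- traj[idx, , drop = FALSE]
  time <- tt[idx]
  sVal <- signal(time)
  sFold <- -2 / (3 * sqrt(3))
  attractor <- integer(nCells)
  region <- character(nCells)
  for (q in seq_len(nCells)) {
    roots <- .cubicRoots(sVal[q])
    x <- coords[q, 1]
    if (length(roots) == 3) {
      attractor[q] <- if (x > roots[2]) 1L else 2L
      stable <- if (x > roots[2]) roots[3] else roots[1]
    } else {
      attractor[q] <- if (sVal[q] < sFold) 2L else 1L
      stable <- roots[1]
    }
    region[q] <- if (abs(x - stable) <= coreWidth) "core" else "transition-layer"
  }
  methods::new("SimulatedDataset", coords = unname(coords), time = time,
               attractor = attractor, region = region,
               params = list(signalRate = signalRate, noise = noise,
                             nCells = nCells, seed = seed, s0 = s0,
                             sEnd = sEnd, dt = dt, sFold = sFold,
                             signalValues = sVal))
}

# --- triple-well benchmark ---------------------------------------------------

#' Three-fold symmetric triple-well potential
#'
#' U(z) = -A sum_k exp(-|z - c_k|^2 / (2 s^2)) + b |z|^4 with the three well
#' centers c_k at radius r and angles 90, 210, 330 degrees. With r^2 > 2 s^2
#' the origin is a local maximum (order-2 saddle) surrounded by the three
#' minima, with one first-order saddle between each pair of adjacent basins.
#' Critical points are refined numerically from their symmetric starting
#' guesses at construction.
#'
#' @param depth well amplitude A
#' @param width well width s
#' @param radius center radius r
#' @param quartic confinement coefficient b
#' @return an [SDEModel-class] (noise slot set to 1; scaled by the caller)
#' @export
tripleWellPotential <- function(depth = 2, width = 0.55, radius = 1.4,
                                quartic = 0.02) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  centers <- radius * cbind(cos(ang), sin(ang))
  U <- function(z) {
    z <- as.numeric(z)
    g <- sum(-depth * exp(-((z[1] - centers[, 1])^2 +
                            (z[2] - centers[, 2])^2) / (2 * width^2)))
    g + quartic * sum(z^2)^2
  }
  gradU <- function(z) {
    z <- as.numeric(z)
    dx <- z[1] - centers[, 1]; dy <- z[2] - centers[, 2]
    e <- exp(-(dx^2 + dy^2) / (2 * width^2))
    gx <- sum(depth * e * dx / width^2) + 4 * quartic * sum(z^2) * z[1]
    gy <- sum(depth * e * dy / width^2) + 4 * quartic * sum(z^2) * z[2]
    c(gx, gy)
  }
  refine <- function(z0) {
    stats::optim(z0, function(z) sum(gradU(z)^2), method = "BFGS",
                 control = list(reltol = 1e-14))$par
  }
  minima <- t(apply(centers, 1, refine))
  midAng <- c(pi / 2 + pi / 3, pi / 2 + pi, pi / 2 + 5 * pi / 3)
  saddleGuess <- radius * cos(pi / 3) * cbind(cos(midAng), sin(midAng))
  saddles <- t(apply(saddleGuess, 1, refine))
  maxima <- matrix(c(0, 0), 1, 2)
  barrier <- U(saddles[1, ]) - U(minima[1, ])
  sdeModel(drift = function(x, t) -gradU(x), noise = function(x, t) 1,
           dim = 2L, potential = U, minima = minima, saddles = saddles,
           maxima = maxima, barrier = barrier)
}

#' Simulate the triple-well transition benchmark
#'
#' Overdamped Langevin dynamics dz = -grad U(z) dt + sqrt(2 eps) dW on the
#' three-fold symmetric triple-well potential; snapshots are sampled
#' uniformly along one long trajectory after a 10 percent burn-in. Ground
#' truth: attractor = basin of the noiseless gradient flow (steepest-descent
#' mapping to a minimum); region = "core" / "saddle" / "transition-layer" by
#' proximity to the nearest critical point (the order-2 maximum at the
#' origin counts as saddle region).
#'
#' @param epsilon noise strength eps
#' @param nCells number of snapshots
#' @param seed integer seed
#' @param nSteps trajectory length in steps
#' @param dt integrator step
#' @param coreRadius,saddleRadius proximity radii for region labels
#' @param potential optionally a custom [SDEModel-class] from
#'   [tripleWellPotential()]
#' @return a [SimulatedDataset-class] with 2-D coords
#' @export
simulateTripleWell <- function(epsilon = 0.45, nCells = 2001L, seed = 1L,
                               nSteps = 200000L, dt = 1e-2,
                               coreRadius = 0.5, saddleRadius = 0.45,
                               potential = NULL) {
  stopifnot(epsilon > 0)
  pot <- if (is.null(potential)) tripleWellPotential() else potential
  model <- sdeModel(drift = pot@drift,
                    noise = function(x, t) sqrt(2 * epsilon), dim = 2L,
                    potential = pot@potential, minima = pot@minima,
                    saddles = pot@saddles, maxima = pot@maxima,
                    barrier = pot@barrier)
  traj <- eulerMaruyama(model, pot@minima[1, ], dt, nSteps, seed = seed)
  tt <- attr(traj, "time")
  burn <- floor(0.1 * nSteps)
  idx <- round(seq(burn + 1L, nSteps + 1L, length.out = nCells))
  coords <- traj[idx, , drop = FALSE]
  time <- tt[idx]
  attractor <- flowBasin(coords, model)
  crit <- rbind(pot@minima, pot@saddles, pot@maxima)
  critKind <- c(rep("core", nrow(pot@minima)),
                rep("saddle", nrow(pot@saddles) + nrow(pot@maxima)))
  critRad <- c(rep(coreRadius, nrow(pot@minima)),
               rep(saddleRadius, nrow(pot@saddles) + nrow(pot@maxima)))
  region <- vapply(seq_len(nCells), function(q) {
    dd <- sqrt(rowSums((crit - matrix(coords[q, ], nrow(crit), 2,
                                      byrow = TRUE))^2))
    k <- which.min(dd)
    if (dd[k] <= critRad[k]) critKind[k] else "transition-layer"
  }, character(1))
  methods::new("SimulatedDataset", coords = unname(coords), time = time,
               attractor = attractor, region = region,
               params = list(epsilon = epsilon, nCells = nCells, seed = seed,
                             nSteps = nSteps, dt = dt,
                             barrier = pot@barrier, minima = pot@minima,
                             saddles = pot@saddles))
}

#' Basin of attraction of the noiseless flow
#'
#' Runs steepest-descent on each sample until it settles near a minimum and
#' returns the index of that minimum.
#'
#' @param coords M x dim sample matrix
#' @param model an [SDEModel-class] with known minima
#' @param stepSize descent step
#' @param nIter descent iterations
#' @return integer basin labels
#' @export
flowBasin <- function(coords, model, stepSize = 0.05, nIter = 400L) {
  z <- as.matrix(coords)
  for (it in seq_len(nIter)) {
    g <- t(apply(z, 1, function(x) model@drift(x, 0)))
    z <- z + stepSize * g
  }
  mins <- model@minima
  apply(z, 1, function(x)
    which.min(colSums((t(mins) - x)^2)))
}

#' Simulate the 1-D double-well benchmark
#'
#' Overdamped Langevin dynamics dx = -U'(x) dt + sqrt(2 eps) dW on the
#' quartic double well U(x) = (x^2 - 1)^2 (minima at +-1, saddle at 0,
#' barrier height 1), sampled uniformly along one long trajectory after a
#' 10 percent burn-in. The escape rate between the wells follows the
#' Kramers/Arrhenius law, making this the canonical fixture for checking
#' that coarse-grained transition probabilities scale as exp(-barrier/eps).
#'
#' @param epsilon noise strength
#' @param nCells number of snapshots
#' @param seed integer seed
#' @param nSteps trajectory length in steps
#' @param dt integrator step
#' @param coreWidth distance to a minimum defining core samples
#' @return a [SimulatedDataset-class] with 1-D coords; the barrier height is
#'   in `params$barrier`
#' @export
simulateDoubleWell <- function(epsilon, nCells = 1500L, seed = 1L,
                               nSteps = 600000L, dt = 5e-3,
                               coreWidth = 0.4) {
  stopifnot(epsilon > 0)
  model <- sdeModel(drift = function(x, t) -4 * x * (x^2 - 1),
                    noise = function(x, t) sqrt(2 * epsilon), dim = 1L,
                    potential = function(x) (x^2 - 1)^2,
                    minima = matrix(c(1, -1), 2, 1),
                    saddles = matrix(0, 1, 1), barrier = 1)
  tr <- eulerMaruyama(model, 1, dt, nSteps, seed = seed)
  burn <- floor(0.1 * nSteps)
  idx <- round(seq(burn + 1L, nSteps + 1L, length.out = nCells))
  x <- tr[idx, , drop = FALSE]
  attractor <- ifelse(x[, 1] > 0, 1L, 2L)
  stable <- ifelse(attractor == 1L, 1, -1)
  region <- ifelse(abs(x[, 1] - stable) <= coreWidth, "core",
                   ifelse(abs(x[, 1]) <= 0.3, "saddle", "transition-layer"))
  methods::new("SimulatedDataset", coords = unname(x),
               time = attr(tr, "time")[idx], attractor = as.integer(attractor),
               region = region,
               params = list(epsilon = epsilon, nCells = nCells, seed = seed,
                             nSteps = nSteps, dt = dt, barrier = 1))
}

# --- toy reversible chains for oracle tests ---------------------------------

#' Toy reversible Markov chains with known structure
#'
#' "birth-death": tridiagonal symmetric weights (closed-form committors);
#' "block": an exactly lumpable chain built from a reversible block-level
#' matrix, so the coarse-graining objective attains 0 at the true partition
#' (truth stored in attributes "blockLabels" and "blockPhat");
#' "random": a dense random symmetric weight matrix.
#'
#' @param type chain family
#' @param size number of states
#' @param seed integer seed
#' @param nBlocks number of blocks for the "block" family
#' @return a [CellRandomWalk-class]
#' @export
toyReversibleChain <- function(type = c("birth-death", "block", "random"),
                               size, seed = 1L, nBlocks = 2L) {
  type <- match.arg(type)
  stopifnot(size >= 2)
  set.seed(seed)
  if (type == "birth-death") {
    w <- matrix(0, size, size)
    wts <- stats::runif(size - 1, 0.2, 1)
    for (i in seq_len(size - 1)) w[i, i + 1] <- w[i + 1, i] <- wts[i]
    return(buildRandomWalk(w))
  }
  if (type == "random") {
    w <- matrix(stats::runif(size * size, 0.05, 1), size, size)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    return(buildRandomWalk(w))
  }
  # block: draw block-level reversible chain and per-state equilibrium shares
  labels <- sort(rep_len(seq_len(nBlocks), size))
  Wb <- matrix(stats::runif(nBlocks^2, 0.2, 1), nBlocks, nBlocks)
  Wb <- (Wb + t(Wb)) / 2
  db <- rowSums(Wb)
  Pb <- Wb / db
  mub <- db / sum(db)
  mu <- stats::runif(size, 0.5, 1.5)
  for (b in seq_len(nBlocks)) {
    inb <- labels == b
    mu[inb] <- mu[inb] / sum(mu[inb]) * mub[b]
  }
  p <- inducedWalk(labels, Pb, mu)
  rw <- methods::new("CellRandomWalk", affinity = unname(mu * p),
                     prob = unname(p), degree = mu, mu = mu)
  attr(rw, "blockLabels") <- labels
  attr(rw, "blockPhat") <- Pb
  rw
}
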