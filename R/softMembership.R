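#' Cell-cluster walk induced by a soft membership
#'
#' ptilde(x,y) = sum_{i,j} rho_i(x) Phat_ij rho_j(y) mu(y)/mutilde_j with
#' mutilde_j = sum_x rho_j(x) mu(x): a jump from x picks its source basin
#' with membership probability, switches basin with the coarse probability,
#' and picks the target cell by membership-weighted equilibrium share. With
#' indicator memberships this reduces exactly to the hard induced walk.
#'
#' @param rho N x K row-simplex membership matrix
#' @param phat K x K row-stochastic coarse transition matrix
#' @param mu strictly positive cell stationary distribution
#' @return row-stochastic N x N matrix
#' @export
inducedSoftWalk <- function(rho, phat, mu) {
  if (min(rho) < -1e-12 || max(abs(rowSums(rho) - 1)) > 1e-8)
    stop("rho rows must lie on the simplex")
  muTilde <- drop(crossprod(rho, mu))
  if (any(muTilde <= 0)) stop("a cluster has zero total membership")
  q <- rho %*% (phat / rep(muTilde, each = nrow(phat)))  # phat %*% diag(1/muTilde)
  tcrossprod(q, rho) * rep(mu, each = length(mu))
}

# Membership objective E[rho] = ||ptilde - p||^2_mu and its gradient in rho,
# evaluated through K x K and N x K contractions only (no dense ptilde):
#   E = tr(U V) - 2 tr(G' R' S R) + C,
#   U = Q' M Q, V = R' M R, Q = R G, G = Phat diag(1/mutilde),
#   M = diag(mu), S = diag(mu) p, C = sum mu(x)/mu(y) p(x,y)^2.
.membershipObjGrad <- function(R, phat, mu, S, constant, gradient = TRUE) {
  muTilde <- drop(crossprod(R, mu))
  G <- phat / rep(muTilde, each = nrow(phat))
  Q <- R %*% G
  MQ <- mu * Q
  MR <- mu * R
  U <- crossprod(Q, MQ)
  V <- crossprod(R, MR)
  SR <- S %*% R
  W <- crossprod(Q, MR)          # Q' M R
  E2core <- crossprod(Q, SR)     # Q' S R
  E <- sum(U * V) - 2 * sum(diag(E2core)) + constant
  if (!gradient) return(list(E = E))
  D2 <- 1 / muTilde^2
  gU <- diag(-(V %*% W %*% phat) %*% diag(D2, length(D2)))
  hS <- diag(-diag(D2, length(D2)) %*% t(phat) %*% crossprod(R, SR))
  grad <- 2 * (MR %*% U) + 2 * (MQ %*% V %*% t(G)) + 2 * outer(mu, gU) -
    2 * (SR %*% t(G) + crossprod(S, R) %*% G) - 2 * outer(mu, hS)
  list(E = E, grad = grad, muTilde = muTilde)
}

#' Refine a hard partition into soft attractor memberships
#'
#' Minimizes E[rho] = ||ptilde(rho) - p||^2_mu over row-simplex memberships
#' with the coarse transition matrix held fixed at its optimum. The simplex
#' constraint is kept exact by parameterizing each row as a normalized
#' exponential of free logits and running limited-memory quasi-Newton
#' (L-BFGS-B) on the logits with the analytic gradient; logits are
#' initialized at margin 6 around the hard labels (membership about 0.995 on
#' the own basin), the closest practical stand-in for an indicator start.
#'
#' @param cg a [CoarseGrainedModel-class] holding the optimal Phat
#' @param rw the underlying [CellRandomWalk-class]
#' @param maxIter iteration cap for the quasi-Newton solver
#' @param margin initial logit margin encoding the hard labels
#' @return a [MembershipModel-class]
#' @export
optimizeMembership <- function(cg, rw, maxIter = 500L, margin = 6) {
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  n <- nrow(p)
  K <- nrow(cg@phat)
  phat <- cg@phat
  S <- mu * p
  constant <- sum((mu * p^2) %*% (1 / mu))
  L0 <- margin * .indicator(cg@labels, K)

  softmaxRows <- function(L) {
    L <- L - apply(L, 1, max)
    E <- exp(L)
    E / rowSums(E)
  }
  fn <- function(l) {
    R <- softmaxRows(matrix(l, n, K))
    .membershipObjGrad(R, phat, mu, S, constant, gradient = FALSE)$E
  }
  gr <- function(l) {
    R <- softmaxRows(matrix(l, n, K))
    og <- .membershipObjGrad(R, phat, mu, S, constant)
    gR <- og$grad
    # chain rule through the row softmax
    gL <- R * (gR - rowSums(R * gR))
    as.vector(gL)
  }
  E0 <- fn(as.vector(L0))
  opt <- stats::optim(as.vector(L0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxIter, factr = 10, pgtol = 1e-8))
  if (!is.finite(opt$value))
    stop("membership objective became non-finite")
  # descent contract: never return something worse than the initialization
  l <- if (opt$value <= E0) opt$par else as.vector(L0)
  E <- min(opt$value, E0)
  rho <- softmaxRows(matrix(l, n, K))
  muTilde <- drop(crossprod(rho, mu))
  methods::new("MembershipModel", rho = rho, muTilde = muTilde,
               entropy = membershipEntropy(rho), objective = E)
}

#' Transition entropy of a membership matrix
#'
#' H(x) = -sum_k rho_k(x) log rho_k(x) (natural log, 0 log 0 = 0); values
#' near 0 mark stable cells, values toward log K mark cells with mixed
#' attractor identity.
#'
#' @param rho N x K row-simplex membership matrix
#' @return length-N entropy vector
#' @export
membershipEntropy <- function(rho) {
  if (min(rho) < -1e-12 || max(abs(rowSums(rho) - 1)) > 1e-8)
    stop("rho rows must lie on the simplex")
  lr <- ifelse(rho > 0, log(rho), 0)
  pmin(pmax(-rowSums(rho * lr), 0), log(ncol(rho)))
}
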