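#' Forward and backward committors on the coarse chain
#'
#' The forward committor q+ is the probability of reaching the target set B
#' before the start set A; it solves (I - Phat) q+ = 0 on states outside
#' A and B with q+ = 0 on A and q+ = 1 on B. The backward committor is
#' computed on the time-reversed chain (and equals 1 - q+ under detailed
#' balance).
#'
#' @param phat K x K row-stochastic transition matrix
#' @param muHat stationary distribution of phat
#' @param A,B disjoint nonempty integer state sets
#' @return list with `qPlus` and `qMinus`
#' @export
committors <- function(phat, muHat, A, B) {
  K <- nrow(phat)
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B) || length(intersect(A, B)))
    stop("A and B must be disjoint and nonempty")
  solveCommittor <- function(P, src0, tgt1) {
    q <- numeric(K)
    q[tgt1] <- 1
    interior <- setdiff(seq_len(K), c(src0, tgt1))
    if (length(interior)) {
      M <- diag(length(interior)) - P[interior, interior, drop = FALSE]
      rhs <- rowSums(P[interior, tgt1, drop = FALSE])
      sol <- tryCatch(solve(M, rhs), error = function(e)
        stop("committor system singular; some states cannot reach A or B ",
             "(chain reducible)"))
      q[interior] <- sol
    }
    q
  }
  qPlus <- solveCommittor(phat, A, B)
  pRev <- t(muHat * phat) / muHat  # reversed chain P~_ij = muHat_j P_ji / muHat_i
  qMinus <- solveCommittor(pRev, B, A)
  list(qPlus = qPlus, qMinus = qMinus)
}

#' Effective current of reactive A -> B trajectories
#'
#' The reactive current f_ij = muHat_i q-_i Phat_ij q+_j (i != j) measures
#' the stationary flow of trajectories on their way from A to B; the
#' effective current is the net part f+_ij = max(f_ij - f_ji, 0). Total flux
#' out of A equals total flux into B.
#'
#' @param phat,muHat coarse chain and its stationary distribution
#' @param qPlus,qMinus committors from [committors()]
#' @return K x K nonnegative matrix with f+_ij * f+_ji = 0
#' @export
effectiveCurrent <- function(phat, muHat, qPlus, qMinus) {
  f <- (muHat * qMinus) * phat * rep(qPlus, each = length(qPlus))
  diag(f) <- 0
  pmax(f - t(f), 0)
}

#' Enumerate transition paths and their likelihoods
#'
#' Enumerates A -> B paths in the digraph of positive effective current.
#' The capacity of a path is its bottleneck (minimum) edge current and the
#' likelihood of a path is its capacity divided by the summed capacity of
#' all enumerated paths. Mode "simple" enumerates every simple path (the
#' default); mode "bottleneck" iteratively extracts the widest path and
#' subtracts its capacity, yielding edge-disjoint dominant channels.
#'
#' @param fPlus effective current matrix
#' @param A,B start and target state sets
#' @param maxPaths guard on the enumeration size (error when exceeded)
#' @param mode "simple" or "bottleneck"
#' @return data.frame with columns `states` (list of integer vectors),
#'   `capacity`, `likelihood`, sorted by descending likelihood
#' @export
enumeratePathLikelihoods <- function(fPlus, A, B, maxPaths = 10000L,
                                     mode = c("simple", "bottleneck")) {
  mode <- match.arg(mode)
  A <- as.integer(A); B <- as.integer(B)
  K <- nrow(fPlus)
  paths <- list(); caps <- numeric()
  if (mode == "simple") {
    count <- 0L
    dfs <- function(path, cap) {
      v <- path[length(path)]
      if (v %in% B) {
        count <<- count + 1L
        if (count > maxPaths) stop("more than ", maxPaths, " paths; raise maxPaths")
        paths[[count]] <<- path
        caps[count] <<- cap
        return(invisible())
      }
      nxt <- which(fPlus[v, ] > 0)
      nxt <- setdiff(nxt, path)
      nxt <- setdiff(nxt, A)
      for (u in nxt) dfs(c(path, u), min(cap, fPlus[v, u]))
    }
    for (a in A) dfs(a, Inf)
  } else {
    f <- fPlus
    repeat {
      wp <- .widestPath(f, A, B)
      if (is.null(wp) || wp$cap <= 0) break
      paths[[length(paths) + 1L]] <- wp$path
      caps <- c(caps, wp$cap)
      for (i in seq_len(length(wp$path) - 1L))
        f[wp$path[i], wp$path[i + 1L]] <- f[wp$path[i], wp$path[i + 1L]] - wp$cap
      if (length(paths) >= maxPaths) break
    }
  }
  if (!length(paths)) {
    warning("no positive-current path from A to B")
    return(data.frame(states = I(list()), capacity = numeric(),
                      likelihood = numeric()))
  }
  lik <- caps / sum(caps)
  o <- order(lik, decreasing = TRUE)
  data.frame(states = I(unname(paths[o])), capacity = caps[o],
             likelihood = lik[o])
}

# Maximum-bottleneck path from A to B (Dijkstra-like widest path).
.widestPath <- function(f, A, B) {
  K <- nrow(f)
  width <- rep(-Inf, K); width[A] <- Inf
  prev <- rep(NA_integer_, K)
  done <- rep(FALSE, K)
  repeat {
    cand <- which(!done)
    if (!length(cand)) break
    v <- cand[which.max(width[cand])]
    if (width[v] <= 0) break
    done[v] <- TRUE
    if (v %in% B) {
      path <- v
      while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
      return(list(path = path, cap = width[v]))
    }
    for (u in which(f[v, ] > 0)) {
      wnew <- min(width[v], f[v, u])
      if (wnew > width[u]) { width[u] <- wnew; prev[u] <- v }
    }
  }
  NULL
}

#' Maximum probability flow tree
#'
#' Global lineage summary: the maximum-weight spanning tree on the symmetric
#' stationary flows phi_ij = muHat_i Phat_ij + muHat_j Phat_ji, oriented
#' away from the chosen root.
#'
#' @param phat,muHat coarse chain and stationary distribution
#' @param root root attractor index
#' @return a [LineageTree-class]
#' @export
maxProbabilityFlowTree <- function(phat, muHat, root) {
  K <- nrow(phat)
  root <- as.integer(root)
  stopifnot(root >= 1, root <= K)
  flow <- muHat * phat + t(muHat * phat)
  diag(flow) <- 0
  g <- igraph::graph_from_adjacency_matrix(flow, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1) stop("flow graph is disconnected")
  tree <- igraph::mst(g, weights = -igraph::E(g)$weight)
  parent <- rep(NA_integer_, K)
  ew <- rep(NA_real_, K)
  bfs <- igraph::bfs(tree, root = root, father = TRUE)
  fathers <- as.integer(bfs$father)
  for (v in seq_len(K)) {
    if (v == root) next
    parent[v] <- fathers[v]
    ew[v] <- flow[v, parent[v]]
  }
  methods::new("LineageTree", root = root, parent = parent, edgeWeight = ew,
               method = "mpft")
}

#' Most probable path tree
#'
#' For every attractor the maximum-probability route from the root on the
#' coarse chain (product of step probabilities), computed as a shortest-path
#' tree under -log Phat edge costs; each state's parent is its predecessor
#' on that route.
#'
#' @param phat coarse transition matrix
#' @param root root attractor index
#' @return a [LineageTree-class]
#' @export
mostProbablePathTree <- function(phat, root) {
  K <- nrow(phat)
  root <- as.integer(root)
  off <- phat
  diag(off) <- 0
  g <- igraph::graph_from_adjacency_matrix(off > 0, mode = "directed")
  costs <- -log(off[off > 0])
  sp <- igraph::shortest_paths(g, from = root, to = igraph::V(g),
                               weights = costs, output = "vpath",
                               mode = "out")
  parent <- rep(NA_integer_, K)
  ew <- rep(NA_real_, K)
  for (v in seq_len(K)) {
    vp <- as.integer(sp$vpath[[v]])
    if (v == root || length(vp) < 2) next
    parent[v] <- vp[length(vp) - 1L]
    ew[v] <- phat[parent[v], v]
  }
  methods::new("LineageTree", root = root, parent = parent, edgeWeight = ew,
               method = "mppt")
}

#' Transition path analysis between attractor sets
#'
#' Runs the committor/current/path-enumeration chain on a coarse-grained
#' model.
#'
#' @param cg a [CoarseGrainedModel-class] (or a [CellFateModel-class])
#' @param A,B start and target attractor sets
#' @param maxPaths,mode passed to [enumeratePathLikelihoods()]
#' @return a [TransitionPathResult-class]
#' @export
transitionPaths <- function(cg, A, B, maxPaths = 10000L, mode = "simple") {
  if (methods::is(cg, "CellFateModel")) cg <- cg@coarse
  q <- committors(cg@phat, cg@muHat, A, B)
  fp <- effectiveCurrent(cg@phat, cg@muHat, q$qPlus, q$qMinus)
  paths <- enumeratePathLikelihoods(fp, A, B, maxPaths = maxPaths, mode = mode)
  methods::new("TransitionPathResult", qPlus = q$qPlus, qMinus = q$qMinus,
               fPlus = fp, paths = paths, A = as.integer(A), B = as.integer(B))
}
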