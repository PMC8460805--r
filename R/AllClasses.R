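#' @useDynLib transcell, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Matrix Matrix
#' @import methods
NULL

setClassUnion("matrixOrSparse", c("matrix", "Matrix"))

#' Expression matrix with cell and gene identifiers
#'
#' Nonnegative cells-by-genes expression values; the sole required input to
#' the multiscale pipeline. Cells are always rows: loaders transpose
#' genes-as-rows inputs at read time so that one orientation holds
#' everywhere.
#'
#' @slot values nonnegative numeric matrix (dense or sparse), cells x genes
#' @slot cellIds character vector of unique cell identifiers
#' @slot geneIds character vector of unique gene identifiers
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrixOrSparse", cellIds = "character",
                 geneIds = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@cellIds))
    msg <- c(msg, "number of rows must equal length(cellIds)")
  if (ncol(v) != length(object@geneIds))
    msg <- c(msg, "number of columns must equal length(geneIds)")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "duplicate cell identifiers")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicate gene identifiers")
  mn <- min(v)  # S4 Summary method handles sparse inputs
  if (is.finite(mn) && mn < 0)
    msg <- c(msg, "expression values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Run configuration for the multiscale pipeline
#'
#' @slot kNeighbors number of nearest neighbours in the affinity graph
#' @slot bandwidthMode "local-adaptive" (per-cell kth-neighbour distance) or
#'   "global" (shared median bandwidth)
#' @slot nAttractors fixed number of attractors (>= 2) or NA for automatic
#'   selection by the eigen-peak index
#' @slot declareMicroStates number of micro-states for pre-aggregation
#'   (0 disables it)
#' @slot seed integer seed controlling every stochastic step
#' @slot tolerances named numeric tolerances
#' @slot embeddingSource "provided" or "pca" for the 2-D manifold coordinates
#' @export
setClass("RunConfig",
  representation(kNeighbors = "integer", bandwidthMode = "character",
                 nAttractors = "integer", declareMicroStates = "integer",
                 seed = "integer", tolerances = "numeric",
                 embeddingSource = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@kNeighbors < 2L) msg <- c(msg, "kNeighbors must be >= 2")
  if (!object@bandwidthMode %in% c("local-adaptive", "global"))
    msg <- c(msg, "bandwidthMode must be 'local-adaptive' or 'global'")
  if (!is.na(object@nAttractors) && object@nAttractors < 2L)
    msg <- c(msg, "nAttractors must be >= 2 when fixed")
  if (object@declareMicroStates < 0L)
    msg <- c(msg, "declareMicroStates must be >= 0")
  if (!object@embeddingSource %in% c("provided", "pca"))
    msg <- c(msg, "embeddingSource must be 'provided' or 'pca'")
  if (length(msg)) msg else TRUE
})

#' Reversible cellular random walk
#'
#' Row-stochastic transition matrix p(x,y) = w(x,y)/d(x) built from a
#' symmetric affinity w, with stationary distribution mu(x) = d(x)/sum(d).
#' The construction enforces detailed balance mu(x)p(x,y) = mu(y)p(y,x).
#'
#' @slot affinity symmetric nonnegative affinity matrix w
#' @slot prob row-stochastic transition matrix p
#' @slot degree row sums d(x) of the affinity
#' @slot mu stationary distribution
#' @export
setClass("CellRandomWalk",
  representation(affinity = "matrix", prob = "matrix", degree = "numeric",
                 mu = "numeric"))

setValidity("CellRandomWalk", function(object) {
  msg <- character()
  p <- object@prob
  mu <- object@mu
  n <- nrow(p)
  if (ncol(p) != n) msg <- c(msg, "transition matrix must be square")
  if (length(mu) != n) msg <- c(msg, "mu length must match matrix dimension")
  if (max(abs(rowSums(p) - 1)) > 1e-10)
    msg <- c(msg, "rows of p must sum to 1 (1e-10)")
  if (any(mu < 0) || abs(sum(mu) - 1) > 1e-10)
    msg <- c(msg, "mu must be a probability distribution")
  db <- max(abs(mu * p - t(mu * p)))
  if (db > 1e-10)
    msg <- c(msg, sprintf("detailed balance violated (residual %.3g)", db))
  if (max(abs(object@affinity - t(object@affinity))) > 1e-10)
    msg <- c(msg, "affinity must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Eigen-spectrum diagnostics for choosing the number of attractors
#'
#' @slot eigenvalues descending real eigenvalues of the cell-cell walk
#' @slot epi eigen-peak index per candidate K (named "2".."kmax")
#' @slot bestK argmax of the eigen-peak index
#' @export
setClass("EigenPeakCurve",
  representation(eigenvalues = "numeric", epi = "numeric", bestK = "integer"))

#' Coarse-grained attractor model
#'
#' Hard partition of cells into K attractor basins with the K x K
#' transition matrix that minimizes the mu-weighted Hilbert-Schmidt
#' distance between the induced and the original cell-cell walk.
#'
#' @slot labels attractor assignment per cell (1..K)
#' @slot phat K x K row-stochastic coarse transition matrix
#' @slot muHat coarse stationary distribution
#' @slot objective final value of the coarse-graining objective J
#' @slot trace per-iteration objective values (non-increasing)
#' @export
setClass("CoarseGrainedModel",
  representation(labels = "integer", phat = "matrix", muHat = "numeric",
                 objective = "numeric", trace = "numeric"))

setValidity("CoarseGrainedModel", function(object) {
  msg <- character()
  K <- nrow(object@phat)
  if (any(tabulate(object@labels, K) == 0L))
    msg <- c(msg, "every cluster must be nonempty")
  if (max(abs(rowSums(object@phat) - 1)) > 1e-10)
    msg <- c(msg, "phat rows must sum to 1")
  st <- max(abs(drop(object@muHat %*% object@phat) - object@muHat))
  if (st > 1e-8) msg <- c(msg, "muHat must be stationary for phat (1e-8)")
  fl <- object@muHat * object@phat
  if (max(abs(fl - t(fl))) > 1e-8)
    msg <- c(msg, "coarse detailed balance violated (1e-8)")
  if (length(msg)) msg else TRUE
})

#' Soft attractor membership of cells
#'
#' @slot rho N x K row-simplex membership matrix
#' @slot muTilde membership-weighted coarse stationary distribution
#' @slot entropy per-cell transition entropy H(x) = -sum rho log rho
#' @slot objective final value of the membership objective E
#' @export
setClass("MembershipModel",
  representation(rho = "matrix", muTilde = "numeric", entropy = "numeric",
                 objective = "numeric"))

setValidity("MembershipModel", function(object) {
  msg <- character()
  r <- object@rho
  if (min(r) < -1e-12) msg <- c(msg, "memberships must be nonnegative")
  if (max(abs(rowSums(r) - 1)) > 1e-10)
    msg <- c(msg, "membership rows must sum to 1")
  K <- ncol(r)
  if (any(object@entropy < -1e-12 | object@entropy > log(K) + 1e-12))
    msg <- c(msg, "entropy out of [0, log K]")
  if (any(object@muTilde <= 0))
    msg <- c(msg, "muTilde must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Transition path decomposition of the coarse chain
#'
#' @slot qPlus forward committor (0 on A, 1 on B)
#' @slot qMinus backward committor
#' @slot fPlus K x K effective (net reactive) current
#' @slot paths data.frame of simple A->B paths with capacity and likelihood
#' @slot A,B start/target state sets
#' @export
setClass("TransitionPathResult",
  representation(qPlus = "numeric", qMinus = "numeric", fPlus = "matrix",
                 paths = "data.frame", A = "integer", B = "integer"))

#' Rooted lineage tree on the coarse chain
#'
#' @slot root root attractor index
#' @slot parent parent of each attractor (NA at the root)
#' @slot edgeWeight weight of the edge to the parent (NA at the root)
#' @slot method "mpft" (maximum probability flow tree) or "mppt"
#'   (most probable path tree)
#' @export
setClass("LineageTree",
  representation(root = "integer", parent = "integer", edgeWeight = "numeric",
                 method = "character"))

#' Two-dimensional cell-fate dynamical manifold
#'
#' Gaussian-mixture stationary density over attractor centers; the landscape
#' is phi(z) = -log p(z) and each cell sits at its membership-weighted
#' transition coordinate.
#'
#' @slot centers K x 2 attractor centers
#' @slot covariances list of K 2x2 SPD covariance matrices
#' @slot weights mixture weights (coarse stationary distribution)
#' @slot xi N x 2 per-cell transition coordinates
#' @slot energy per-cell landscape value phi(xi(x))
#' @export
setClass("DynamicalManifold",
  representation(centers = "matrix", covariances = "list",
                 weights = "numeric", xi = "matrix", energy = "numeric"))

setValidity("DynamicalManifold", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "mixture weights must sum to 1")
  for (S in object@covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) msg <- c(msg, "covariances must be positive definite")
  }
  if (any(!is.finite(object@energy)))
    msg <- c(msg, "energy must be finite on the data")
  if (length(msg)) msg else TRUE
})

#' Per-transition cell analysis (transition cell score and layer)
#'
#' @slot pair the (i, j) attractor pair, i the departing state
#' @slot cells indices of relevant cells, ordered by descending score
#' @slot cellIds identifiers of the relevant cells in the same order
#' @slot tau transition cell score per relevant cell
#' @slot logisticFit named vector (r0, s) of the fitted logistic over ranks
#' @slot transitionMask TRUE for cells inside the transition band
#' @export
setClass("TransitionAnalysis",
  representation(pair = "integer", cells = "integer", cellIds = "character",
                 tau = "numeric", logisticFit = "numeric",
                 transitionMask = "logical"))

#' Gene classification for one transition
#'
#' @slot pair the (i, j) attractor pair
#' @slot table data.frame with columns gene, label, statistic, p_adj
#' @export
setClass("GeneClassification",
  representation(pair = "integer", table = "data.frame"))

#' Micro-state aggregation of a cellular random walk
#'
#' @slot microLabels micro-state assignment per cell
#' @slot walk the aggregated random walk over micro-states
#' @slot centers micro-state centroid coordinates
#' @slot sizes cells per micro-state
#' @export
setClass("MicroStateModel",
  representation(microLabels = "integer", walk = "CellRandomWalk",
                 centers = "matrix", sizes = "integer"))

#' Stochastic differential equation model for snapshot simulation
#'
#' @slot drift function f(x, t) giving the drift vector
#' @slot noise function sigma(x, t) giving the noise amplitude
#' @slot dim state dimension
#' @slot potential optional potential function U(x) (drift = -grad U)
#' @slot minima matrix of known minima (rows), if a potential is given
#' @slot saddles matrix of known first-order saddles (rows)
#' @slot maxima matrix of known local maxima (rows)
#' @slot barrier barrier height between a minimum and the adjacent saddle
#' @export
setClass("SDEModel",
  representation(drift = "function", noise = "function", dim = "integer",
                 potential = "ANY", minima = "matrix", saddles = "matrix",
                 maxima = "matrix", barrier = "numeric"))

#' Simulated snapshot dataset with ground truth
#'
#' @slot coords N x dim snapshot states (pseudo-cells)
#' @slot time per-sample time stamp
#' @slot attractor ground-truth basin label of the noiseless flow
#' @slot region "core", "saddle" or "transition-layer"
#' @slot params model parameters and seed used
#' @export
setClass("SimulatedDataset",
  representation(coords = "matrix", time = "numeric", attractor = "integer",
                 region = "character", params = "list"))

#' Fitted multiscale cell-fate model
#'
#' Container tying together the cellular random walk, the coarse-grained
#' attractor model, the soft membership and the spectrum diagnostics for one
#' dataset, plus the low-dimensional coordinates used along the way.
#'
#' @slot randomWalk the cell-cell (or micro-state) random walk
#' @slot coarse the coarse-grained attractor model
#' @slot membership the soft membership model
#' @slot spectrum eigen-peak diagnostics (may be empty when K was fixed)
#' @slot coords low-dimensional coordinates the affinity was built on
#' @slot coords2d 2-D coordinates for manifold construction
#' @slot cellIds cell identifiers
#' @slot microLabels micro-state assignment when aggregation was used
#'   (length 0 otherwise); model-level results are broadcast through it
#' @export
setClass("CellFateModel",
  representation(randomWalk = "CellRandomWalk", coarse = "CoarseGrainedModel",
                 membership = "MembershipModel", spectrum = "EigenPeakCurve",
                 coords = "matrix", coords2d = "matrix", cellIds = "character",
                 microLabels = "integer"))
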