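#' Aggregate cells into micro-states
#'
#' Seeded centroid (k-means) clustering of the low-dimensional coordinates
#' into `kMicro` micro-states. Should a cluster come back empty it is
#' re-seeded from the point farthest from its assigned centroid and the
#' clustering re-run once.
#'
#' @param coords N x d coordinates
#' @param kMicro number of micro-states, 2 <= kMicro < N (kMicro = N gives
#'   the identity aggregation)
#' @param seed integer seed
#' @param nstart k-means restarts
#' @return list with `labels` (length N) and `centers` (kMicro x d)
#' @export
aggregateCells <- function(coords, kMicro, seed = 1L, nstart = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (kMicro > n) stop("kMicro must not exceed the number of cells")
  if (kMicro < 2) stop("kMicro must be >= 2")
  if (kMicro == n)
    return(list(labels = seq_len(n), centers = coords))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = kMicro, nstart = nstart, iter.max = 100L)
  if (any(tabulate(km$cluster, kMicro) == 0L)) {
    far <- order(-sqrt(rowSums((coords - km$centers[km$cluster, ])^2)))
    init <- coords[far[seq_len(kMicro)], , drop = FALSE]
    km <- stats::kmeans(coords, centers = init, iter.max = 100L)
  }
  list(labels = km$cluster, centers = km$centers)
}

#' Micro-state transition probabilities from a cell walk
#'
#' Mu-weighted aggregation of the cell-cell walk onto a micro-state
#' partition: p_micro(a,b) = sum_{x in a, y in b} mu(x) p(x,y) / mu_micro(a)
#' with mu_micro(a) = sum_{x in a} mu(x) -- the same lumping algebra as the
#' coarse-graining step, so aggregating cells to micro-states and
#' micro-states to attractors equals aggregating cells to attractors
#' directly. The aggregated flux is symmetric whenever the cell walk is
#' reversible, so the result is again a valid reversible walk and feeds the
#' standard pipeline unchanged.
#'
#' @param rw a [CellRandomWalk-class]
#' @param microLabels micro-state assignment per cell
#' @param centers optional micro-state coordinates to carry along
#' @return a [MicroStateModel-class]
#' @export
microTransitionProbabilities <- function(rw, microLabels, centers = NULL) {
  microLabels <- as.integer(microLabels)
  kM <- max(microLabels)
  sizes <- tabulate(microLabels, kM)
  if (any(sizes == 0L)) stop("empty micro-state in partition")
  p <- transitionMatrix(rw)
  mu <- stationaryDist(rw)
  bf <- .blockFlux(microLabels, p, mu, kM)
  flux <- as.matrix(bf$flux)
  flux <- (flux + t(flux)) / 2  # exact symmetry under detailed balance
  muMicro <- bf$muHat
  pMicro <- flux / muMicro
  # the aggregated walk: affinity = flux, degree = muMicro (up to the total)
  walk <- methods::new("CellRandomWalk", affinity = unname(flux),
                       prob = unname(pMicro), degree = muMicro,
                       mu = muMicro / sum(muMicro))
  if (is.null(centers)) centers <- matrix(numeric(0), 0, 0)
  methods::new("MicroStateModel", microLabels = microLabels, walk = walk,
               centers = as.matrix(centers), sizes = as.integer(sizes))
}
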