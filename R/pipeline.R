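#' Fit the multiscale cell-fate model
#'
#' End-to-end pipeline: (optional) preprocessing, kNN Gaussian affinity,
#' reversible cellular random walk, eigen-peak choice of K (unless fixed),
#' optional micro-state aggregation, coarse-grained attractor model and soft
#' membership refinement. Accepts an [ExpressionMatrix-class] (preprocessed
#' internally) or a plain coordinate matrix used as-is.
#'
#' @param x an [ExpressionMatrix-class] or an N x d numeric coordinate matrix
#' @param config a [RunConfig-class]
#' @param coords2d optional N x 2 embedding for downstream manifold work
#'   (required when `config@embeddingSource == "provided"`)
#' @param kmax largest candidate K for automatic selection
#' @param preprocessArgs list of arguments passed to
#'   [preprocessExpression()] when `x` is an expression matrix
#' @return a [CellFateModel-class]
#' @export
fitDynamics <- function(x, config = runConfig(), coords2d = NULL, kmax = 8L,
                        preprocessArgs = list()) {
  if (methods::is(x, "ExpressionMatrix")) {
    pp <- do.call(preprocessExpression, c(list(x), preprocessArgs))
    coords <- pp$coords
    ids <- cellIds(x)
    if (is.null(coords2d)) coords2d <- pp$coords2d
  } else {
    coords <- as.matrix(x)
    ids <- if (!is.null(rownames(coords))) rownames(coords)
           else paste0("cell_", seq_len(nrow(coords)))
    if (is.null(coords2d))
      coords2d <- coords[, seq_len(min(2L, ncol(coords))), drop = FALSE]
  }
  if (config@embeddingSource == "provided" && is.null(coords2d))
    stop("embeddingSource is 'provided' but no coords2d given")
  if (config@kNeighbors >= nrow(coords))
    stop("kNeighbors must be smaller than the number of cells")

  w <- buildAffinity(coords, config@kNeighbors, config@bandwidthMode)
  rw <- buildRandomWalk(w)

  microLabels <- integer(0)
  walk <- rw
  if (config@declareMicroStates > 0L) {
    agg <- aggregateCells(coords, config@declareMicroStates,
                          seed = config@seed)
    ms <- microTransitionProbabilities(rw, agg$labels, agg$centers)
    microLabels <- ms@microLabels
    walk <- ms@walk
    coords2d <- rowsum(as.matrix(coords2d), microLabels) /
      as.vector(table(microLabels))
  }

  spectrum <- methods::new("EigenPeakCurve", eigenvalues = numeric(0),
                           epi = numeric(0), bestK = NA_integer_)
  K <- config@nAttractors
  if (is.na(K)) {
    spectrum <- eigenPeakIndex(walk, kmax = min(kmax, nrow(walk@prob) - 1L))
    K <- spectrum@bestK
  }
  cg <- optimizePartition(walk, K, seed = config@seed)
  mm <- optimizeMembership(cg, walk)
  methods::new("CellFateModel", randomWalk = walk, coarse = cg,
               membership = mm, spectrum = spectrum,
               coords = unname(as.matrix(coords)),
               coords2d = unname(as.matrix(coords2d)), cellIds = ids,
               microLabels = microLabels)
}

#' Write pipeline results to a directory
#'
#' Writes attractors.csv (cell_id, attractor), membership.csv (cell_id,
#' rho_1..rho_K), entropy.csv, phat.csv, muhat.csv, eigenvalues.csv and
#' epi.csv (when automatic K selection ran), manifold.csv (cell_id, xi_1,
#' xi_2, energy) plus landscape_grid.csv when a manifold is given,
#' paths.json when a path result is given, and the configuration echoed as
#' config.yaml.
#'
#' @param model a [CellFateModel-class]
#' @param dir output directory (created if needed)
#' @param manifold optional [DynamicalManifold-class]
#' @param pathResult optional [TransitionPathResult-class]
#' @param config optional [RunConfig-class] to echo
#' @return `dir`, invisibly
#' @export
writeResults <- function(model, dir, manifold = NULL, pathResult = NULL,
                         config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cellIds(model)
  lab <- attractorLabels(model)
  rho <- membershipMatrix(model)
  K <- ncol(rho)
  data.table::fwrite(data.frame(cell_id = ids, attractor = lab),
                     file.path(dir, "attractors.csv"))
  mem <- data.frame(cell_id = ids, rho)
  colnames(mem) <- c("cell_id", paste0("rho_", seq_len(K)))
  data.table::fwrite(mem, file.path(dir, "membership.csv"))
  data.table::fwrite(data.frame(cell_id = ids,
                                entropy = transitionEntropy(model)),
                     file.path(dir, "entropy.csv"))
  data.table::fwrite(as.data.frame(model@coarse@phat),
                     file.path(dir, "phat.csv"), col.names = FALSE)
  data.table::fwrite(data.frame(muhat = model@coarse@muHat),
                     file.path(dir, "muhat.csv"))
  if (length(model@microLabels)) {
    data.table::fwrite(data.frame(cell_id = ids,
                                  micro_state = model@microLabels),
                       file.path(dir, "micro_states.csv"))
  }
  if (length(model@spectrum@eigenvalues)) {
    data.table::fwrite(data.frame(eigenvalue = model@spectrum@eigenvalues),
                       file.path(dir, "eigenvalues.csv"))
    data.table::fwrite(data.frame(K = as.integer(names(model@spectrum@epi)),
                                  epi = model@spectrum@epi),
                       file.path(dir, "epi.csv"))
  }
  if (!is.null(manifold)) {
    xi <- manifold@xi
    if (nrow(xi) == length(lab) && length(model@microLabels))
      xi <- xi  # already per micro-state; broadcast below if needed
    if (nrow(xi) != length(ids) && length(model@microLabels))
      xi <- xi[model@microLabels, , drop = FALSE]
    en <- if (length(manifold@energy) == length(ids)) manifold@energy
          else manifold@energy[model@microLabels]
    data.table::fwrite(data.frame(cell_id = ids, xi_1 = xi[, 1],
                                  xi_2 = xi[, 2], energy = en),
                       file.path(dir, "manifold.csv"))
    data.table::fwrite(landscapeGrid(manifold),
                       file.path(dir, "landscape_grid.csv"))
  }
  if (!is.null(pathResult)) {
    pj <- list(A = pathResult@A, B = pathResult@B,
               paths = lapply(seq_len(nrow(pathResult@paths)), function(r)
                 list(states = pathResult@paths$states[[r]],
                      capacity = pathResult@paths$capacity[r],
                      likelihood = pathResult@paths$likelihood[r])))
    jsonlite::write_json(pj, file.path(dir, "paths.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(config)) {
    yaml::write_yaml(list(k_neighbors = config@kNeighbors,
                          bandwidth_mode = config@bandwidthMode,
                          n_attractors = if (is.na(config@nAttractors)) "auto"
                                         else config@nAttractors,
                          declare_micro_states = config@declareMicroStates,
                          seed = config@seed,
                          embedding_source = config@embeddingSource),
                     file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Write per-transition analysis files
#'
#' tcs_<i>_<j>.csv (cell_id, tau, is_transition) and genes_<i>_<j>.csv
#' (gene, label, statistic, p_adj).
#'
#' @param ta a [TransitionAnalysis-class]
#' @param dir output directory
#' @param genes optional [GeneClassification-class]
#' @return `dir`, invisibly
#' @export
writeTransitionAnalysis <- function(ta, dir, genes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(ta@pair[1], "_", ta@pair[2])
  data.table::fwrite(data.frame(cell_id = ta@cellIds, tau = ta@tau,
                                is_transition = ta@transitionMask),
                     file.path(dir, paste0("tcs_", tag, ".csv")))
  if (!is.null(genes))
    data.table::fwrite(genes@table,
                       file.path(dir, paste0("genes_", tag, ".csv")))
  invisible(dir)
}
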