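#' @rdname accessors
#' @export
setMethod("transitionMatrix", "CellRandomWalk", function(object, ...) object@prob)

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "CoarseGrainedModel", function(object, ...) object@phat)

#' @rdname accessors
#' @export
setMethod("stationaryDist", "CellRandomWalk", function(object, ...) object@mu)

#' @rdname accessors
#' @export
setMethod("stationaryDist", "CoarseGrainedModel", function(object, ...) object@muHat)

#' @rdname accessors
#' @export
setMethod("affinityMatrix", "CellRandomWalk", function(object, ...) object@affinity)

#' @rdname accessors
#' @export
setMethod("attractorLabels", "CoarseGrainedModel", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setMethod("attractorLabels", "CellFateModel", function(object, ...) {
  lab <- object@coarse@labels
  if (length(object@microLabels)) lab[object@microLabels] else lab
})

#' @rdname accessors
#' @export
setMethod("membershipMatrix", "MembershipModel", function(object, ...) object@rho)

#' @rdname accessors
#' @export
setMethod("membershipMatrix", "CellFateModel", function(object, ...) {
  r <- object@membership@rho
  if (length(object@microLabels)) r[object@microLabels, , drop = FALSE] else r
})

#' @rdname accessors
#' @export
setMethod("transitionEntropy", "MembershipModel", function(object, ...) object@entropy)

#' @rdname accessors
#' @export
setMethod("transitionEntropy", "CellFateModel", function(object, ...) {
  h <- object@membership@entropy
  if (length(object@microLabels)) h[object@microLabels] else h
})

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object, ...) object@values)

#' @rdname accessors
#' @export
setMethod("cellIds", "ExpressionMatrix", function(object, ...) object@cellIds)

#' @rdname accessors
#' @export
setMethod("cellIds", "CellFateModel", function(object, ...) object@cellIds)

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object, ...) object@geneIds)

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "cells x",
      ncol(object@values), "genes",
      if (methods::is(object@values, "Matrix")) "(sparse)\n" else "(dense)\n")
})

setMethod("show", "CellRandomWalk", function(object) {
  n <- nrow(object@prob)
  cat("CellRandomWalk on", n, "cells\n")
  cat("  detailed-balance residual:",
      format(max(abs(object@mu * object@prob - t(object@mu * object@prob))),
             digits = 3), "\n")
})

setMethod("show", "CoarseGrainedModel", function(object) {
  K <- nrow(object@phat)
  cat("CoarseGrainedModel with", K, "attractors\n")
  cat("  sizes:", paste(tabulate(object@labels, K), collapse = ", "), "\n")
  cat("  objective J:", format(object@objective, digits = 6), "\n")
})

setMethod("show", "MembershipModel", function(object) {
  cat("MembershipModel:", nrow(object@rho), "cells x", ncol(object@rho),
      "attractors; objective E:", format(object@objective, digits = 6), "\n")
  cat("  mean transition entropy:", format(mean(object@entropy), digits = 4), "\n")
})

setMethod("show", "EigenPeakCurve", function(object) {
  cat("EigenPeakCurve over K =", names(object@epi)[1], "..",
      names(object@epi)[length(object@epi)], "\n")
  cat("  best K:", object@bestK, "\n")
})

setMethod("show", "TransitionPathResult", function(object) {
  cat("TransitionPathResult A={", paste(object@A, collapse = ","), "} -> B={",
      paste(object@B, collapse = ","), "}: ", nrow(object@paths),
      " path(s)\n", sep = "")
})

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree (", object@method, ") rooted at ", object@root, "\n", sep = "")
})

setMethod("show", "DynamicalManifold", function(object) {
  cat("DynamicalManifold with", nrow(object@centers), "attractors;",
      nrow(object@xi), "cells\n")
})

setMethod("show", "TransitionAnalysis", function(object) {
  cat("TransitionAnalysis ", object@pair[1], " -> ", object@pair[2], ": ",
      length(object@tau), " relevant cells, ", sum(object@transitionMask),
      " in transition layer\n", sep = "")
})

setMethod("show", "GeneClassification", function(object) {
  cat("GeneClassification ", object@pair[1], " -> ", object@pair[2], ":\n", sep = "")
  print(table(object@table$label))
})

setMethod("show", "MicroStateModel", function(object) {
  cat("MicroStateModel:", length(object@sizes), "micro-states over",
      length(object@microLabels), "cells\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nrow(object@coords), "samples in",
      ncol(object@coords), "dimension(s);", length(unique(object@attractor)),
      "ground-truth basins\n")
})

setMethod("show", "CellFateModel", function(object) {
  cat("CellFateModel on", length(object@cellIds), "cells\n")
  show(object@coarse)
  cat("  mean transition entropy:",
      format(mean(transitionEntropy(object)), digits = 4), "\n")
})
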