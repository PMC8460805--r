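#' Construct an ExpressionMatrix
#'
#' @param values nonnegative numeric matrix, cells as rows
#' @param cellIds,geneIds identifiers; taken from dimnames when missing
#' @return a validated [ExpressionMatrix-class]
#' @export
expressionMatrix <- function(values, cellIds = rownames(values),
                             geneIds = colnames(values)) {
  if (is.null(cellIds)) cellIds <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(geneIds)) geneIds <- paste0("gene_", seq_len(ncol(values)))
  methods::new("ExpressionMatrix", values = values,
               cellIds = as.character(cellIds), geneIds = as.character(geneIds))
}

#' Construct a run configuration
#'
#' @param kNeighbors neighbours in the affinity graph
#' @param bandwidthMode "local-adaptive" or "global"
#' @param nAttractors number of attractors, or "auto" / NA for eigen-peak
#'   selection
#' @param declareMicroStates micro-states for pre-aggregation (0 = off)
#' @param seed integer seed
#' @param tolerances named numeric vector of tolerances
#' @param embeddingSource "pca" or "provided"
#' @return a validated [RunConfig-class]
#' @export
runConfig <- function(kNeighbors = 30L, bandwidthMode = "local-adaptive",
                      nAttractors = "auto", declareMicroStates = 0L,
                      seed = 1L, tolerances = c(objective = 1e-10),
                      embeddingSource = "pca") {
  if (identical(nAttractors, "auto")) nAttractors <- NA_integer_
  methods::new("RunConfig", kNeighbors = as.integer(kNeighbors),
               bandwidthMode = bandwidthMode,
               nAttractors = as.integer(nAttractors),
               declareMicroStates = as.integer(declareMicroStates),
               seed = as.integer(seed), tolerances = tolerances,
               embeddingSource = embeddingSource)
}

#' Load an expression matrix
#'
#' Supported formats: delimited text (header row = gene ids, first column =
#' cell ids), MatrixMarket triplets with `barcodes.tsv` and
#' `genes.tsv`/`features.tsv` sidecars, and an HDF5 single-cell container
#' (h5ad dialect: `X`, `obs/_index`, `var/_index`; requires the rhdf5
#' package). Cells are rows everywhere; a genes-as-rows MTX (the common
#' convention) is transposed at load.
#'
#' @param path input file
#' @param format "csv", "tsv", "mtx" or "h5"; guessed from the extension by
#'   default
#' @return an [ExpressionMatrix-class]
#' @export
loadExpression <- function(path, format = c("auto", "csv", "tsv", "mtx", "h5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     h5 = "h5", h5ad = "h5", stop("cannot guess format from '.", ext, "'"))
  }
  em <- switch(format,
    csv = .loadDelim(path, ","),
    tsv = .loadDelim(path, "\t"),
    mtx = .loadMtx(path),
    h5 = .loadH5(path))
  methods::validObject(em)
  em
}

.loadDelim <- function(path, sep) {
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
    error = function(e) stop("malformed file '", path, "': ", conditionMessage(e)))
  if (ncol(dt) < 2) stop("malformed file '", path, "': need id column plus data")
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1] + 1L
    stop("malformed file '", path, "': non-numeric entries in column ", bad)
  }
  rownames(vals) <- ids
  expressionMatrix(vals, cellIds = ids, geneIds = colnames(vals))
}

.loadMtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed MTX '", path, "': ",
                                         conditionMessage(e)))
  dir <- dirname(path)
  bcFile <- file.path(dir, "barcodes.tsv")
  gFile <- Filter(file.exists, file.path(dir, c("genes.tsv", "features.tsv")))
  if (!file.exists(bcFile) || length(gFile) == 0)
    stop("MTX sidecars barcodes.tsv and genes.tsv/features.tsv not found in ", dir)
  barcodes <- readLines(bcFile)
  genes <- vapply(strsplit(readLines(gFile[1]), "\t"), `[`, character(1), 1)
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)  # genes-as-rows convention: transpose to cells-as-rows
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stop("MTX dimensions ", nrow(m), "x", ncol(m),
         " match neither orientation of the sidecars (",
         length(barcodes), " barcodes, ", length(genes), " genes)")
  }
  m <- methods::as(m, "CsparseMatrix")
  expressionMatrix(m, cellIds = barcodes, geneIds = genes)
}

.loadH5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5 containers requires the 'rhdf5' package")
  ls <- rhdf5::h5ls(path)
  X <- rhdf5::h5read(path, "X")
  obs <- as.character(rhdf5::h5read(
    path, if ("/obs" %in% paste0(ls$group, "/", ls$name) ||
              any(ls$name == "_index" & ls$group == "/obs")) "obs/_index" else "obs_names"))
  var <- as.character(rhdf5::h5read(
    path, if (any(ls$name == "_index" & ls$group == "/var")) "var/_index" else "var_names"))
  X <- as.matrix(X)
  # h5ad stores X as obs x var but HDF5 column-major readback transposes it
  if (nrow(X) == length(var) && ncol(X) == length(obs)) X <- t(X)
  expressionMatrix(X, cellIds = obs, geneIds = var)
}

#' Save an expression matrix
#'
#' Writes csv/tsv (header = gene ids, first column = cell ids) or a
#' MatrixMarket file with sidecars, inverting [loadExpression()] exactly.
#'
#' @param em an [ExpressionMatrix-class]
#' @param path output file
#' @param format "csv", "tsv" or "mtx"
#' @export
saveExpression <- function(em, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  v <- exprValues(em)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = cellIds(em), as.matrix(v), check.names = FALSE)
    colnames(df) <- c("cell_id", geneIds(em))
    data.table::fwrite(df, path, sep = sep)
  } else {
    m <- methods::as(methods::as(Matrix::Matrix(Matrix::t(v), sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(m, path)
    writeLines(cellIds(em), file.path(dirname(path), "barcodes.tsv"))
    writeLines(geneIds(em), file.path(dirname(path), "genes.tsv"))
  }
  invisible(path)
}

#' Preprocess an expression matrix
#'
#' Conventional light preprocessing ahead of affinity construction: per-cell
#' scaling to the median library size, log1p, selection of the most variable
#' genes (zero-variance genes always drop out here), and projection onto the
#' leading principal components. Every step can be disabled; with all steps
#' off the input is returned unchanged and used directly as coordinates.
#'
#' @param em an [ExpressionMatrix-class]
#' @param normalize scale each cell to the median library size
#' @param logTransform apply log1p
#' @param nTopGenes keep this many most-variable genes (NULL keeps all genes,
#'   still dropping zero-variance ones when any filtering/PCA is active)
#' @param nComponents number of principal components (NULL disables PCA)
#' @return list with `expression` (processed [ExpressionMatrix-class]),
#'   `coords` (N x d matrix used for affinities) and `coords2d` (first two
#'   columns of `coords`)
#' @export
preprocessExpression <- function(em, normalize = TRUE, logTransform = TRUE,
                                 nTopGenes = 2000L, nComponents = 30L) {
  v <- as.matrix(exprValues(em))
  if (normalize) {
    lib <- rowSums(v)
    if (any(lib == 0)) stop("all-zero cells: ", paste(cellIds(em)[lib == 0],
                                                      collapse = ", "))
    v <- v / lib * stats::median(lib)
  }
  if (logTransform) v <- log1p(v)
  keep <- seq_len(ncol(v))
  if (!is.null(nTopGenes) || !is.null(nComponents)) {
    vars <- apply(v, 2, stats::var)
    keep <- which(vars > 0)
    if (!is.null(nTopGenes) && length(keep) > nTopGenes)
      keep <- keep[order(vars[keep], decreasing = TRUE)[seq_len(nTopGenes)]]
    keep <- sort(keep)
    v <- v[, keep, drop = FALSE]
  }
  out <- expressionMatrix(v, cellIds = cellIds(em), geneIds = geneIds(em)[keep])
  coords <- v
  if (!is.null(nComponents)) {
    d <- min(nComponents, nrow(v) - 1L)
    if (ncol(v) < d)
      stop("fewer genes (", ncol(v), ") than requested components (", d, ")")
    pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = d)
    coords <- pc$x
    # fix component signs so the projection is platform-deterministic
    for (j in seq_len(ncol(coords))) {
      i <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[i, j] < 0) coords[, j] <- -coords[, j]
    }
  }
  coords2d <- coords[, seq_len(min(2L, ncol(coords))), drop = FALSE]
  list(expression = out, coords = unname(coords), coords2d = unname(coords2d))
}
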