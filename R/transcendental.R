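#' Transition cell score and ordering for one attractor pair
#'
#' For the transition from attractor i to attractor j, a cell is relevant
#' when rho_i + rho_j >= relevanceThreshold; for relevant cells the score
#' tau_ij(x) = rho_i(x) / (rho_i(x) + rho_j(x)) measures the relative
#' position between the two basins (1 = firmly in i, 0 = firmly in j).
#' Relevant cells are ordered by descending tau (ties by cell index), the
#' descent of tau over ranks is fitted with a logistic curve, and cells with
#' tau strictly inside (bandLow, bandHigh) form the transition layer.
#'
#' @param model a [CellFateModel-class], or an N x K membership matrix
#' @param i,j departing and arriving attractor indices
#' @param relevanceThreshold minimum rho_i + rho_j for a cell to enter the
#'   analysis
#' @param bandLow,bandHigh open tau band defining transition cells
#' @param ids optional cell identifiers (taken from the model if present)
#' @return a [TransitionAnalysis-class]
#' @export
transitionCellScore <- function(model, i, j, relevanceThreshold = 0.8,
                                bandLow = 0.1, bandHigh = 0.9, ids = NULL) {
  if (methods::is(model, "CellFateModel")) {
    rho <- membershipMatrix(model)
    if (is.null(ids)) ids <- cellIds(model)
  } else rho <- as.matrix(model)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rho)))
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("i and j must differ")
  rel <- which(rho[, i] + rho[, j] >= relevanceThreshold)
  if (!length(rel))
    stop("no cells relevant to transition ", i, " -> ", j,
         "; lower relevanceThreshold")
  tau <- rho[rel, i] / (rho[rel, i] + rho[rel, j])
  o <- order(-tau, rel)
  rel <- rel[o]; tau <- tau[o]
  fit <- if (length(tau) >= 10L)
    fitTransitionLayer(tau, bandLow = bandLow, bandHigh = bandHigh)
  else  # too few cells for a meaningful logistic; band-only mask
    list(params = c(r0 = NA_real_, s = NA_real_),
         mask = tau > bandLow & tau < bandHigh)
  methods::new("TransitionAnalysis", pair = c(i, j), cells = as.integer(rel),
               cellIds = ids[rel], tau = unname(tau), logisticFit = fit$params,
               transitionMask = fit$mask)
}

#' Fit a logistic transition layer to an ordered score sequence
#'
#' Least-squares fit of tau(r) = 1 / (1 + exp((r - r0)/s)) over ranks r of
#' the descending score sequence. The transition mask is the open band
#' bandLow < tau < bandHigh regardless of the fit, so a failed fit degrades
#' gracefully (with a warning) to the band-only mask.
#'
#' @param tau descending score sequence
#' @param bandLow,bandHigh open band defining transition cells
#' @return list with `params` (named vector r0, s, converged flag as attr),
#'   `mask` (logical), `abundance` (share of cells in the layer) and
#'   `sharpness` (s / n)
#' @export
fitTransitionLayer <- function(tau, bandLow = 0.1, bandHigh = 0.9) {
  n <- length(tau)
  if (n < 10L) stop("need at least 10 relevant cells")
  r <- seq_len(n)
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(tau ~ 1 / (1 + exp((r - r0) / s)),
                           start = list(r0 = n / 2, s = max(n / 20, 1)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(m)
  }, error = function(e) {
    warning("logistic fit did not converge; using band-only transition mask")
    c(r0 = NA_real_, s = NA_real_)
  })
  mask <- tau > bandLow & tau < bandHigh
  list(params = c(r0 = unname(fit[["r0"]]), s = unname(fit[["s"]])),
       mask = mask, abundance = mean(mask),
       sharpness = unname(fit[["s"]]) / n)
}

#' Classify transition-driver, meta-stable and intermediate-hybrid genes
#'
#' For one ordered transition (see [transitionCellScore()]):
#' transition-driver (TD) genes track the score itself -- absolute Spearman
#' correlation between expression and tau over the transition-layer cells at
#' least `tdCorThreshold`. The remaining candidates come from rank-sum
#' differential expression between the two stable sides (BH-adjusted at
#' `fdr`): a DE gene whose expression in the stable cells of the side it
#' marks is also significantly higher than in the transition cells is
#' meta-stable (MS); a DE gene that stays expressed in the transition cells
#' is intermediate-hybrid (IH). Direction "-down" marks the departing state
#' i (high tau), "-up" the arriving state j. Precedence TD > MS > IH.
#'
#' @param expr an [ExpressionMatrix-class] (cells x genes)
#' @param ta a [TransitionAnalysis-class]
#' @param tdCorThreshold Spearman threshold for TD genes
#' @param fdr BH-adjusted significance level for the rank-sum tests
#' @return a [GeneClassification-class]; genes with label "none" are omitted
#' @export
classifyGenes <- function(expr, ta, tdCorThreshold = 0.5, fdr = 0.05) {
  v <- as.matrix(exprValues(expr))[ta@cells, , drop = FALSE]
  genes <- geneIds(expr)
  tau <- ta@tau
  mask <- ta@transitionMask
  stableI <- !mask & tau >= 0.5   # stable cells of the departing side
  stableJ <- !mask & tau < 0.5    # stable cells of the arriving side
  if (!any(stableI) || !any(stableJ))
    stop("need stable cells on both sides of the transition")
  keep <- which(colSums(v) > 0)
  if (length(keep) < ncol(v))
    message(ncol(v) - length(keep), " all-zero gene(s) excluded")
  out <- data.frame(gene = character(), label = character(),
                    statistic = numeric(), p_adj = numeric())

  # TD: expression follows tau within the transition layer
  tdStat <- rep(NA_real_, ncol(v))
  if (any(mask)) {
    tdStat[keep] <- vapply(keep, function(g)
      suppressWarnings(stats::cor(v[mask, g], tau[mask], method = "spearman")),
      numeric(1))
  }
  isTD <- !is.na(tdStat) & abs(tdStat) >= tdCorThreshold

  # DE between the stable sides
  pDE <- rep(NA_real_, ncol(v))
  pDE[keep] <- vapply(keep, function(g)
    suppressWarnings(stats::wilcox.test(v[stableI, g], v[stableJ, g],
                                        exact = FALSE)$p.value), numeric(1))
  pAdj <- stats::p.adjust(pDE, method = "BH")
  isDE <- !is.na(pAdj) & pAdj <= fdr

  labels <- rep("none", ncol(v))
  stat <- rep(NA_real_, ncol(v))
  padjOut <- rep(NA_real_, ncol(v))
  for (g in keep) {
    if (isTD[g]) {
      labels[g] <- "TD"; stat[g] <- tdStat[g]
      next
    }
    if (!isDE[g]) next
    up <- mean(v[stableJ, g]) > mean(v[stableI, g])  # marks arriving side?
    side <- if (up) stableJ else stableI
    dir <- if (up) "up" else "down"
    pvsT <- if (any(mask))
      suppressWarnings(stats::wilcox.test(v[side, g], v[mask, g],
                                          alternative = "greater",
                                          exact = FALSE)$p.value)
    else 0  # no transition layer: stable-exclusive by definition
    if (!is.na(pvsT) && pvsT <= fdr) labels[g] <- paste0("MS-", dir)
    else labels[g] <- paste0("IH-", dir)
    stat[g] <- suppressWarnings(
      stats::wilcox.test(v[stableI, g], v[stableJ, g], exact = FALSE)$statistic)
    padjOut[g] <- pAdj[g]
  }
  tab <- data.frame(gene = genes, label = labels, statistic = stat,
                    p_adj = padjOut)[labels != "none", , drop = FALSE]
  rownames(tab) <- NULL
  methods::new("GeneClassification", pair = ta@pair, table = tab)
}
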