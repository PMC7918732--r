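#' @useDynLib epigrn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' InferenceConfig: parameters of the tree-ensemble inference
#'
#' @slot nTrees number of regression trees per target (default 1000).
#' @slot kMode candidate features per split: \code{"ALL"} (every candidate
#'   regulator, the pipeline's convention) or \code{"SQRT"}.
#' @slot seed integer seed; one seed drives all resampling and split
#'   randomness, and results are bit-identical for a fixed seed regardless of
#'   the order targets are processed in or the number of workers.
#' @slot minVariance genes whose (sample) variance is at or below this are
#'   flagged constant: skipped as targets and excluded as predictors.
#' @slot bootstrap whether each tree resamples the samples with replacement.
#' @slot minLeaf minimum number of samples in a leaf (regression random-forest
#'   convention, default 5); set to 1 to grow trees to purity.
#' @slot maxDepth maximum tree depth (0 = no depth limit); depth 1 gives
#'   stumps.
#' @seealso [inferenceConfig()], [inferNetwork()]
#' @export
setClass("InferenceConfig",
         representation(nTrees = "integer", kMode = "character",
                        seed = "integer", minVariance = "numeric",
                        bootstrap = "logical", minLeaf = "integer",
                        maxDepth = "integer"))

setValidity("InferenceConfig", function(object) {
  msgs <- character()
  if (object@nTrees < 1L) msgs <- c(msgs, "nTrees must be >= 1")
  if (!object@kMode %in% c("ALL", "SQRT")) msgs <- c(msgs, "kMode must be ALL or SQRT")
  if (object@minVariance < 0) msgs <- c(msgs, "minVariance must be >= 0")
  if (object@minLeaf < 1L) msgs <- c(msgs, "minLeaf must be >= 1")
  if (object@maxDepth < 0L) msgs <- c(msgs, "maxDepth must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an inference configuration
#'
#' @param nTrees,kMode,seed,minVariance,bootstrap,minLeaf,maxDepth see
#'   [InferenceConfig-class].
#' @return an [InferenceConfig-class] object.
#' @export
inferenceConfig <- function(nTrees = 1000, kMode = c("ALL", "SQRT"), seed = 42,
                            minVariance = 1e-12, bootstrap = TRUE,
                            minLeaf = 5, maxDepth = 0) {
  new("InferenceConfig", nTrees = as.integer(nTrees),
      kMode = match.arg(kMode), seed = as.integer(seed),
      minVariance = as.numeric(minVariance), bootstrap = isTRUE(bootstrap),
      minLeaf = as.integer(minLeaf), maxDepth = as.integer(maxDepth))
}

.rowVar <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Normalize an expression matrix for inference
#'
#' Centers every gene row to mean zero and scales rows whose sample variance
#' exceeds \code{minVariance} to unit variance; rows at or below the threshold
#' are set to zero and flagged constant (attribute \code{"constantGenes"}, a
#' named logical). The operation is idempotent up to floating point.
#'
#' @param m numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns; no missing values, at least two samples.
#' @param minVariance constant-gene variance threshold.
#' @return the normalized matrix, with attribute \code{"constantGenes"}.
#' @export
normalizeExpression <- function(m, minVariance = 1e-12) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
  v <- .rowVar(m)
  const <- v <= minVariance
  out <- m - rowMeans(m)
  out[!const, ] <- out[!const, , drop = FALSE] / sqrt(v[!const])
  out[const, ] <- 0
  structure(out, constantGenes = stats::setNames(const, rownames(m)))
}

.asExprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment")) {
    expr <- SummarizedExperiment::assay(expr, 1L)
  }
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicated gene ids in matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicated sample ids in matrix")
  rownames(expr) <- toupper(rownames(expr))
  expr
}

#' Infer a weighted regulator-to-target network
#'
#' For every non-constant gene g, an ensemble of regression trees predicts g's
#' unit-variance expression from all candidate regulators except g itself. The
#' weight of edge r -> g is the importance of r: the total variance reduction
#' over all splits on r across all trees, divided by the number of trees.
#' Regulators can themselves be targets of other regulators; self-edges are
#' excluded; zero-weight pairs are dropped.
#'
#' Samples and candidate predictors are canonicalised internally (sorted by
#' id) and each target draws its randomness from a stream derived from its
#' gene id and the seed, so permuting sample columns or gene rows, processing
#' order, and worker count leave the result bit-identical.
#'
#' @param expr numeric genes x samples matrix (rownames/colnames required) or
#'   a \code{SummarizedExperiment} (first assay used).
#' @param regulators a [RegulatorSet-class]; at least two regulator genes must
#'   be present in the matrix.
#' @param config an [InferenceConfig-class].
#' @param nCores targets may be scored on several workers; the result is
#'   independent of this value.
#' @return a [GRNetwork-class] with edges sorted by weight descending.
#' @examples
#' spec <- syntheticGRNSpec(nTF = 6, nEpi = 2, nTargets = 20, nSamples = 60,
#'                          seed = 1)
#' net <- generateTrueNetwork(spec)
#' expr <- simulateExpression(net, spec)
#' rs <- regulatorSetFromTruth(net)
#' grn <- inferNetwork(expr, rs, inferenceConfig(nTrees = 50, seed = 1))
#' grn
#' @export
inferNetwork <- function(expr, regulators, config = inferenceConfig(),
                         nCores = 1L) {
  stopifnot(is(regulators, "RegulatorSet"), is(config, "InferenceConfig"))
  validObject(config)
  expr <- .asExprMatrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  norm <- normalizeExpression(expr, config@minVariance)
  const <- attr(norm, "constantGenes")
  regPresent <- sort(intersect(geneIds(regulators), rownames(norm)))
  if (length(regPresent) < 2L)
    stop("fewer than 2 regulator genes present in the expression matrix")
  regPool <- regPresent[!const[regPresent]]
  targetsAll <- rownames(norm)[!const]
  tnorm <- t(norm)  # samples x genes

  scoreTarget <- function(g) {
    preds <- setdiff(regPool, g)
    if (!length(preds)) return(NULL)
    k <- if (config@kMode == "ALL") length(preds)
         else max(1L, as.integer(round(sqrt(length(preds)))))
    w <- .forestImportance(tnorm[, preds, drop = FALSE], tnorm[, g],
                           config@nTrees, k, config@maxDepth,
                           config@bootstrap, config@minLeaf, config@seed, g)
    keep <- w > 0
    if (!any(keep)) return(NULL)
    data.frame(regulator = preds[keep], target = g, weight = w[keep])
  }

  res <- if (nCores > 1L) {
    parallel::mclapply(targetsAll, scoreTarget, mc.cores = nCores)
  } else {
    lapply(targetsAll, scoreTarget)
  }
  ed <- do.call(rbind, res)
  if (is.null(ed))
    ed <- data.frame(regulator = character(), target = character(),
                     weight = numeric())
  ed <- ed[order(-ed$weight, ed$regulator, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  new("GRNetwork", edges = ed, regulatorUniverse = regPresent)
}

#' Trim a network to its top-weight fraction
#'
#' Ranks all edges by weight (largest to smallest) and retains exactly
#' \code{ceiling(fraction * nEdges)} of them — the high-confidence network.
#' Ties at the cutoff are broken deterministically by (weight descending,
#' regulator id ascending, target id ascending).
#'
#' @param g a [GRNetwork-class] (or [Subnetwork-class]; the class is kept).
#' @param fraction in (0, 1]; the pipeline's convention is 0.1.
#' @return a network of the same class with the retained edges.
#' @export
trimTopFraction <- function(g, fraction = 0.1) {
  stopifnot(is(g, "GRNetwork"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  e <- g@edges
  if (!nrow(e)) stop("cannot trim an empty network")
  keep <- max(1L, as.integer(ceiling(fraction * nrow(e) - 1e-9)))
  o <- order(-e$weight, e$regulator, e$target)
  e <- e[o[seq_len(keep)], , drop = FALSE]
  rownames(e) <- NULL
  initialize(g, edges = e)
}
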