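#' @import methods
NULL

.REG_CLASSES <- c("TF", "EPIGENETIC")
.EPI_CATEGORIES <- c("HISTONE_MODIFICATION", "DNA_METHYLATION",
                     "CHROMATIN_REMODELING", "SIRNA")
.CATEGORIES <- c(.EPI_CATEGORIES, "NONE")

.checkGeneIds <- function(ids, what = "gene id") {
  bad <- character()
  if (any(is.na(ids) | !nzchar(ids)))
    bad <- c(bad, sprintf("empty %s(s) present", what))
  if (any(ids != toupper(ids)))
    bad <- c(bad, sprintf("%ss must be stored uppercase", what))
  bad
}

#' RegulatorSet: a validated collection of regulator records
#'
#' Holds the curated predictor genes used for network inference: transcription
#' factors and/or epigenetic regulators, the latter annotated with a functional
#' category (histone modification, DNA methylation, chromatin remodeling, or
#' siRNA biogenesis).
#'
#' @slot records a data.frame with columns \code{gene}, \code{symbol},
#'   \code{regClass} (\code{"TF"} or \code{"EPIGENETIC"}) and \code{category}
#'   (one of the four epigenetic categories, or \code{"NONE"} for TFs).
#' @seealso [loadRegulators()], [countByCategory()]
#' @export
setClass("RegulatorSet", representation(records = "data.frame"))

setValidity("RegulatorSet", function(object) {
  rec <- object@records
  need <- c("gene", "symbol", "regClass", "category")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  msgs <- .checkGeneIds(rec$gene)
  dup <- unique(rec$gene[duplicated(rec$gene)])
  if (length(dup))
    msgs <- c(msgs, sprintf("duplicate gene id(s): %s",
                            paste(dup, collapse = ", ")))
  if (!all(rec$regClass %in% .REG_CLASSES))
    msgs <- c(msgs, "regClass must be TF or EPIGENETIC")
  if (!all(rec$category %in% .CATEGORIES))
    msgs <- c(msgs, "unknown category value")
  if (any(rec$regClass == "EPIGENETIC" & rec$category == "NONE"))
    msgs <- c(msgs, "EPIGENETIC records must carry a category")
  if (any(rec$regClass == "TF" & rec$category != "NONE"))
    msgs <- c(msgs, "TF records must have category NONE")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' GRNetwork: a weighted regulator-to-target network
#'
#' The central object of the pipeline: a directed graph whose edges carry
#' tree-ensemble importance scores ("weights") interpreted as confidence of a
#' regulatory relationship. Regulators are drawn from a declared universe (the
#' predictor set used at inference time); targets may themselves be regulators,
#' but self-edges are forbidden.
#'
#' @slot edges a data.frame with columns \code{regulator}, \code{target}
#'   (character gene ids) and \code{weight} (non-negative numeric).
#' @slot regulatorUniverse character vector of all candidate regulator ids.
#' @seealso [inferNetwork()], [trimTopFraction()], [extractSubnetwork()]
#' @export
setClass("GRNetwork",
         representation(edges = "data.frame", regulatorUniverse = "character"))

setValidity("GRNetwork", function(object) {
  e <- object@edges
  need <- c("regulator", "target", "weight")
  if (!all(need %in% names(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(e)) {
    if (any(e$regulator == e$target)) msgs <- c(msgs, "self-edges are forbidden")
    if (any(e$weight < 0) || any(!is.finite(e$weight)))
      msgs <- c(msgs, "weights must be finite and non-negative")
    if (!all(e$regulator %in% object@regulatorUniverse))
      msgs <- c(msgs, "edge regulator outside the regulator universe")
    if (anyDuplicated(paste0(e$regulator, "\r", e$target)))
      msgs <- c(msgs, "at most one edge per (regulator, target) pair")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Subnetwork: edges of a parent network restricted to a DEG target list
#'
#' A GRNetwork whose targets are restricted to a supplied list of
#' differentially expressed genes (DEGs); the regulators themselves need not be
#' differentially expressed. Keeps the DEG list and the parent label as
#' provenance.
#'
#' @slot degList character vector of the DEG ids used as the target filter.
#' @slot parentLabel single string naming the source network.
#' @seealso [extractSubnetwork()], [rankRegulators()], [weightFraction()]
#' @export
setClass("Subnetwork", contains = "GRNetwork",
         representation(degList = "character", parentLabel = "character"))

setValidity("Subnetwork", function(object) {
  if (nrow(object@edges) && !all(object@edges$target %in% object@degList))
    return("every subnetwork edge target must be in the DEG list")
  TRUE
})

#' RegulatorRanking: regulators ordered by weight sum within a subnetwork
#'
#' For each regulator with at least one edge in a subnetwork, the sum of its
#' edge weights (its influence statistic) and its rank, 1 = most influential.
#' Ties in weight sum are broken by gene id so that ranks are a permutation.
#'
#' @slot table data.frame with columns \code{regulator}, \code{symbol},
#'   \code{regClass}, \code{weightSum}, \code{rank}, \code{globalRank}
#'   (pre-filter rank; equals \code{rank} for an unfiltered ranking).
#' @slot label single string naming the ranking (typically the DEG study).
#' @seealso [rankRegulators()], [filterRanking()], [rankSumAggregate()]
#' @export
setClass("RegulatorRanking",
         representation(table = "data.frame", label = "character"))

setValidity("RegulatorRanking", function(object) {
  t <- object@table
  need <- c("regulator", "weightSum", "rank", "globalRank")
  if (!all(need %in% names(t)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  msgs <- character()
  if (nrow(t)) {
    if (is.unsorted(-t$weightSum)) msgs <- c(msgs, "not sorted by weightSum descending")
    if (!identical(t$rank, seq_len(nrow(t)))) msgs <- c(msgs, "rank must be 1..n")
    if (any(t$weightSum < 0)) msgs <- c(msgs, "weight sums must be non-negative")
    if (anyDuplicated(t$regulator)) msgs <- c(msgs, "duplicated regulator")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CumulativeRanking: rank-sum aggregation of several regulator rankings
#'
#' Summarises two or more top-n regulator lists into one cumulative order: for
#' every regulator appearing in at least one list's top n, the sum of its ranks
#' across lists (absent-from-top-n contributes rank n + 1), sorted ascending.
#'
#' @slot table data.frame with columns \code{regulator}, \code{rankSum},
#'   \code{cumulativeRank}, \code{totalWeightSum}.
#' @slot nLists number of aggregated rankings.
#' @slot topN the per-list truncation depth used.
#' @seealso [rankSumAggregate()]
#' @export
setClass("CumulativeRanking",
         representation(table = "data.frame", nLists = "integer",
                        topN = "integer"))

#' TargetSet: the in silico targets of one regulator
#'
#' The set of target genes a regulator points to in a (trimmed) network: the
#' targets of all edges whose regulator is the gene of interest.
#'
#' @slot regulator single gene id.
#' @slot targets character vector of target gene ids (never containing the
#'   regulator itself).
#' @slot sourceLabel string naming the network the set came from.
#' @seealso [getTargets()], [hypergeomOverlap()]
#' @export
setClass("TargetSet",
         representation(regulator = "character", targets = "character",
                        sourceLabel = "character"))

setValidity("TargetSet", function(object) {
  if (length(object@regulator) != 1L) return("exactly one regulator id")
  if (object@regulator %in% object@targets)
    return("regulator cannot be among its own targets")
  TRUE
})

#' Background: the gene universe for a hypergeometric overlap test
#'
#' Either a genome-wide universe given by its size alone, or a microarray probe
#' set given by its member genes (in which case both target lists are first
#' intersected with the members and the probe count is the background size).
#'
#' @slot kind \code{"GENOME"} or \code{"PROBESET"}.
#' @slot size positive integer, the background population size.
#' @slot members gene ids on the array (required for \code{PROBESET}).
#' @seealso [genomeBackground()], [probesetBackground()], [hypergeomOverlap()]
#' @export
setClass("Background",
         representation(kind = "character", size = "integer",
                        members = "character"))

setValidity("Background", function(object) {
  if (!object@kind %in% c("GENOME", "PROBESET")) return("kind must be GENOME or PROBESET")
  if (length(object@size) != 1L || is.na(object@size) || object@size < 1L)
    return("size must be a positive integer")
  if (object@kind == "PROBESET") {
    if (!length(object@members)) return("PROBESET background requires members")
    if (object@size != length(unique(object@members)))
      return("PROBESET size must equal the number of distinct members")
  }
  TRUE
})

#' SyntheticGRNSpec: parameters of the synthetic benchmark generator
#'
#' Describes a ground-truth regulator-to-target network and its expression
#' readout: network size and sparsity, planted process-regulator hubs whose
#' targets concentrate in a "process module" (the ground-truth DEG list),
#' linear effect sizes, Gaussian noise, and sample count.
#'
#' @slot nTF,nEpi numbers of TF and epigenetic regulators.
#' @slot nTargets number of non-regulator genes.
#' @slot outDegreeMean mean number of background targets per regulator.
#' @slot nProcessRegulators number of planted hub regulators.
#' @slot processModuleSize size of the planted module.
#' @slot hubConcentration fraction of module driver edges originating from hubs.
#' @slot effectLow,effectHigh range of absolute linear effect sizes.
#' @slot noiseSD standard deviation of the additive Gaussian noise.
#' @slot nSamples number of simulated samples.
#' @slot seed integer seed; all generation is a pure function of (spec, seed).
#' @seealso [syntheticGRNSpec()], [generateTrueNetwork()], [simulateExpression()]
#' @export
setClass("SyntheticGRNSpec",
         representation(nTF = "integer", nEpi = "integer", nTargets = "integer",
                        outDegreeMean = "numeric",
                        nProcessRegulators = "integer",
                        processModuleSize = "integer",
                        hubConcentration = "numeric",
                        effectLow = "numeric", effectHigh = "numeric",
                        noiseSD = "numeric", nSamples = "integer",
                        seed = "integer"))

setValidity("SyntheticGRNSpec", function(object) {
  msgs <- character()
  if (object@nTF + object@nEpi < 1L) msgs <- c(msgs, "need at least one regulator")
  if (object@nProcessRegulators > object@nTF + object@nEpi)
    msgs <- c(msgs, "more process regulators than regulators")
  if (object@processModuleSize > object@nTargets)
    msgs <- c(msgs, "process module larger than available targets")
  if (object@hubConcentration < 0 || object@hubConcentration > 1)
    msgs <- c(msgs, "hubConcentration must lie in [0, 1]")
  if (object@effectLow <= 0 || object@effectHigh < object@effectLow)
    msgs <- c(msgs, "need 0 < effectLow <= effectHigh")
  if (object@noiseSD < 0) msgs <- c(msgs, "noiseSD must be non-negative")
  if (object@nSamples < 2L) msgs <- c(msgs, "need at least two samples")
  if (object@outDegreeMean <= 0) msgs <- c(msgs, "outDegreeMean must be positive")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TrueNetwork: a planted ground-truth network
#'
#' The generator's output: signed linear effects on a DAG over regulators and
#' targets, plus the identity of the planted process regulators and the process
#' module (the ground-truth DEG list). Genes are stored in topological order.
#'
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{effect} (signed real).
#' @slot genes all gene ids, in a topological order of the DAG.
#' @slot regulatorClasses named character vector, \code{"TF"}/\code{"EPIGENETIC"}
#'   per regulator id.
#' @slot processRegulators ids of the planted hubs.
#' @slot processModule ids of the planted module genes.
#' @seealso [generateTrueNetwork()], [simulateExpression()], [makeDegList()],
#'   [auprAgainstTruth()]
#' @export
setClass("TrueNetwork",
         representation(edges = "data.frame", genes = "character",
                        regulatorClasses = "character",
                        processRegulators = "character",
                        processModule = "character"))

setValidity("TrueNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("regulator", "target", "effect") %in% names(e)))
    return("edges must have columns regulator, target, effect")
  pos <- match(object@genes, object@genes)
  if (nrow(e)) {
    i <- match(e$regulator, object@genes); j <- match(e$target, object@genes)
    if (any(is.na(i)) || any(is.na(j)))
      msgs <- c(msgs, "edge endpoints outside the gene universe")
    else if (any(i >= j))
      msgs <- c(msgs, "edges must respect the stored topological order (DAG)")
  }
  if (!all(object@processModule %in% object@genes))
    msgs <- c(msgs, "process module outside the gene universe")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
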