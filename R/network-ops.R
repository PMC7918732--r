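#' Extract the subnetwork regulating a DEG list
#'
#' Restricts a network to the edges whose target gene is in the supplied list
#' of differentially expressed genes. The regulators themselves are not
#' required to be differentially expressed. An empty result is allowed (with a
#' warning), e.g. when the DEG list is disjoint from all targets.
#'
#' @param g a [GRNetwork-class] (typically the trimmed high-confidence network).
#' @param degs nonempty character vector of DEG ids.
#' @param label name for the resulting subnetwork (e.g. the DEG study).
#' @return a [Subnetwork-class].
#' @export
extractSubnetwork <- function(g, degs, label = "subnetwork") {
  stopifnot(is(g, "GRNetwork"))
  degs <- unique(toupper(degs))
  if (!length(degs)) stop("DEG list is empty")
  e <- g@edges[g@edges$target %in% degs, , drop = FALSE]
  rownames(e) <- NULL
  if (!nrow(e))
    warning("no edges of '", label, "' target the supplied DEG list")
  new("Subnetwork", edges = e, regulatorUniverse = g@regulatorUniverse,
      degList = sort(degs), parentLabel = label)
}

#' Rank regulators of a subnetwork by weight sum
#'
#' Sums the weight of all edges in the subnetwork for every regulator and
#' ranks regulators from highest to lowest weight sum. Ties are broken by gene
#' id (ascending), so ranks are a permutation of 1..n and downstream rank-sum
#' aggregation is well defined.
#'
#' @param s a nonempty [Subnetwork-class] (any [GRNetwork-class] accepted).
#' @param regulators optional [RegulatorSet-class] used to annotate symbols and
#'   regulator classes.
#' @param label ranking label; defaults to the subnetwork's parent label.
#' @return a [RegulatorRanking-class].
#' @export
rankRegulators <- function(s, regulators = NULL, label = NULL) {
  stopifnot(is(s, "GRNetwork"))
  e <- s@edges
  if (!nrow(e)) stop("cannot rank regulators of an empty subnetwork")
  ws <- tapply(e$weight, e$regulator, sum)
  tab <- data.frame(regulator = names(ws), weightSum = as.numeric(ws))
  tab <- tab[order(-tab$weightSum, tab$regulator), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$globalRank <- tab$rank
  tab$symbol <- ""
  tab$regClass <- NA_character_
  if (!is.null(regulators)) {
    stopifnot(is(regulators, "RegulatorSet"))
    i <- match(tab$regulator, geneIds(regulators))
    tab$symbol <- ifelse(is.na(i), "", records(regulators)$symbol[i])
    tab$regClass <- records(regulators)$regClass[i]
  }
  tab <- tab[, c("regulator", "symbol", "regClass", "weightSum", "rank",
                 "globalRank")]
  rownames(tab) <- NULL
  if (is.null(label))
    label <- if (is(s, "Subnetwork")) s@parentLabel else "network"
  new("RegulatorRanking", table = tab, label = label)
}

#' Filter a regulator ranking by class and truncate
#'
#' Keeps only regulators of the requested class (as annotated by the supplied
#' regulator set), preserves their relative order, truncates to \code{topN},
#' and re-ranks 1..k within the filtered list while retaining the original
#' global rank in the \code{globalRank} column.
#'
#' @param r a [RegulatorRanking-class].
#' @param regulators a [RegulatorSet-class] giving class membership.
#' @param regClass \code{"ALL"}, \code{"TF"} or \code{"EPIGENETIC"}.
#' @param topN maximum entries kept (no padding if fewer remain).
#' @return a [RegulatorRanking-class].
#' @export
filterRanking <- function(r, regulators,
                          regClass = c("ALL", "TF", "EPIGENETIC"),
                          topN = 25L) {
  stopifnot(is(r, "RegulatorRanking"), is(regulators, "RegulatorSet"))
  regClass <- match.arg(regClass)
  if (topN < 1L) stop("topN must be >= 1")
  tab <- r@table
  i <- match(tab$regulator, geneIds(regulators))
  tab$symbol <- ifelse(is.na(i), tab$symbol, records(regulators)$symbol[i])
  tab$regClass <- records(regulators)$regClass[i]
  if (regClass != "ALL")
    tab <- tab[!is.na(tab$regClass) & tab$regClass == regClass, , drop = FALSE]
  tab <- utils::head(tab, topN)
  tab$globalRank <- tab$rank
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("RegulatorRanking", table = tab,
      label = sprintf("%s[%s,top%d]", r@label, regClass, topN))
}

#' Aggregate regulator rankings with a rank-sum
#'
#' Combines two or more regulator rankings into one cumulative order. The
#' candidate set is the union of the top-\code{topN} regulators across lists;
#' each candidate's rank sum is the sum of its per-list ranks, where a
#' regulator absent from a list's top \code{topN} contributes rank
#' \code{topN + 1} (the minimal penalty that keeps sums comparable). Sorted by
#' rank sum ascending; ties are broken by total weight sum (descending), then
#' gene id. The output does not depend on the order the lists are given in.
#'
#' @param rankings list of at least two [RegulatorRanking-class] objects.
#' @param topN per-list truncation depth (the pipeline's convention is 25).
#' @param fullRanks if \code{TRUE}, use each regulator's rank within the full
#'   input ranking instead of the truncated list (absence from the full list
#'   contributes its length + 1); the candidate set is unchanged.
#' @return a [CumulativeRanking-class].
#' @export
rankSumAggregate <- function(rankings, topN = 25L, fullRanks = FALSE) {
  if (!is.list(rankings) || length(rankings) < 2L)
    stop("need at least 2 rankings to aggregate")
  stopifnot(all(vapply(rankings, is, TRUE, "RegulatorRanking")))
  topN <- as.integer(topN)
  if (topN < 1L) stop("topN must be >= 1")
  tops <- lapply(rankings, function(r) utils::head(r@table, topN))
  cand <- sort(unique(unlist(lapply(tops, `[[`, "regulator"))))
  rankOf <- function(r, top) {
    if (fullRanks) {
      i <- match(cand, r@table$regulator)
      ifelse(is.na(i), nrow(r@table) + 1L, r@table$rank[i])
    } else {
      i <- match(cand, top$regulator)
      ifelse(is.na(i), topN + 1L, top$rank[i])
    }
  }
  rmat <- mapply(rankOf, rankings, tops)
  wmat <- vapply(rankings, function(r) {
    i <- match(cand, r@table$regulator)
    ifelse(is.na(i), 0, r@table$weightSum[i])
  }, numeric(length(cand)))
  tab <- data.frame(regulator = cand,
                    rankSum = as.integer(rowSums(rmat)),
                    totalWeightSum = rowSums(wmat))
  tab <- tab[order(tab$rankSum, -tab$totalWeightSum, tab$regulator), ,
             drop = FALSE]
  tab$cumulativeRank <- seq_len(nrow(tab))
  tab <- tab[, c("regulator", "rankSum", "cumulativeRank", "totalWeightSum")]
  rownames(tab) <- NULL
  new("CumulativeRanking", table = tab, nLists = length(rankings),
      topN = topN)
}

#' Retrieve the in silico targets of a regulator
#'
#' Selects all edges whose regulatory gene is the regulator of interest; the
#' targets of those edges constitute the regulator's in silico target set.
#'
#' @param g a [GRNetwork-class].
#' @param regulator gene id.
#' @param sourceLabel provenance label stored in the result.
#' @return a [TargetSet-class]; empty (with a warning) if the regulator has no
#'   edges in the network.
#' @export
getTargets <- function(g, regulator, sourceLabel = "network") {
  stopifnot(is(g, "GRNetwork"), length(regulator) == 1L)
  regulator <- toupper(regulator)
  tg <- g@edges$target[g@edges$regulator == regulator]
  if (!length(tg))
    warning("regulator ", regulator, " has no edges in the network")
  new("TargetSet", regulator = regulator, targets = sort(unique(tg)),
      sourceLabel = sourceLabel)
}

#' Fraction of subnetwork edge weight carried by a target subset
#'
#' The summed weight of edges whose target lies in \code{subset}, divided by
#' the total edge weight of the subnetwork. For any partition of the targets
#' the fractions sum to one.
#'
#' @param s a nonempty [GRNetwork-class]/[Subnetwork-class].
#' @param subset character vector of target gene ids.
#' @return a number in [0, 1].
#' @export
weightFraction <- function(s, subset) {
  stopifnot(is(s, "GRNetwork"))
  e <- s@edges
  total <- sum(e$weight)
  if (!nrow(e) || total <= 0)
    stop("subnetwork has zero total edge weight")
  sum(e$weight[e$target %in% toupper(subset)]) / total
}
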