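#' Area under the precision-recall curve against a planted network
#'
#' Ranks every candidate regulator-to-target pair (regulators = the truth's
#' regulator set, targets = every other gene; pairs absent from the inferred
#' network get weight 0) by inferred weight and computes the area under the
#' precision-recall curve with the planted edges as positives. Tied weights
#' are handled as blocks with the standard continuous interpolation between
#' operating points (precision within a block follows the hyperbolic path, so
#' a single all-tied block integrates exactly to the prevalence). The result
#' is invariant to monotone transformations of the weights.
#'
#' @param inferred a [GRNetwork-class].
#' @param truth a nonempty [TrueNetwork-class] sharing the gene universe.
#' @return AUPR in [0, 1].
#' @export
auprAgainstTruth <- function(inferred, truth) {
  stopifnot(is(inferred, "GRNetwork"), is(truth, "TrueNetwork"))
  if (!nrow(truth@edges)) stop("truth network has no edges")
  regs <- names(truth@regulatorClasses)
  genes <- truth@genes
  key <- function(r, t) paste0(r, "\r", t)
  cand <- expand.grid(regulator = regs, target = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$regulator != cand$target, , drop = FALSE]
  w <- numeric(nrow(cand))
  i <- match(key(cand$regulator, cand$target),
             key(inferred@edges$regulator, inferred@edges$target))
  w[!is.na(i)] <- inferred@edges$weight[i[!is.na(i)]]
  pos <- key(cand$regulator, cand$target) %in%
    key(truth@edges$regulator, truth@edges$target)
  .auprFromScores(w, pos)
}

# Block-wise PR integration with hyperbolic within-block interpolation
# (TP and FP accrue proportionally inside a tied block).
.auprFromScores <- function(scores, positive) {
  P <- sum(positive)
  if (!P) stop("no positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- positive[o]
  blockEnd <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[blockEnd]
  nn <- blockEnd
  auc <- 0; tp0 <- 0; n0 <- 0
  for (b in seq_along(blockEnd)) {
    dtp <- tp[b] - tp0; dn <- nn[b] - n0
    if (dtp > 0) {
      slope <- dtp / dn
      auc <- auc + if (n0 == 0) (dtp / P) * slope else
        (dtp / P) * (slope + (tp0 - n0 * slope) * log((n0 + dn) / n0) / dn)
    }
    tp0 <- tp[b]; n0 <- nn[b]
  }
  auc
}

#' Fraction of planted regulators recovered in the top k
#'
#' @param ranking a [RegulatorRanking-class].
#' @param planted nonempty character vector of planted regulator ids.
#' @param k ranking depth (>= 1).
#' @return |top-k regulators intersect planted| / |planted|.
#' @export
recoveryAtK <- function(ranking, planted, k = 5L) {
  stopifnot(is(ranking, "RegulatorRanking"))
  planted <- unique(toupper(planted))
  if (!length(planted)) stop("planted set is empty")
  if (k < 1L) stop("k must be >= 1")
  top <- utils::head(ranking@table$regulator, k)
  length(intersect(top, planted)) / length(planted)
}

#' Compare two regulator rankings
#'
#' Quantifies how similar two subnetwork rankings are: the overlap and Jaccard
#' index of their top-\code{topN} regulator sets, and the squared Pearson
#' correlations (r^2) of ranks and of weight sums over all regulators common
#' to both full rankings. Because r^2 alone hides anti-correlation (a reversed
#' ranking also has r^2 = 1), the signed correlations are reported alongside.
#' With fewer than 3 common regulators the correlation fields are NA (with a
#' warning); the overlap is still reported.
#'
#' @param a,b [RegulatorRanking-class] objects.
#' @param topN depth of the top-set comparison.
#' @return list with \code{overlapTopN}, \code{jaccardTopN}, \code{r2Ranks},
#'   \code{r2WeightSums}, \code{corRanks}, \code{corWeightSums},
#'   \code{nCommon}.
#' @export
compareRankings <- function(a, b, topN = 25L) {
  stopifnot(is(a, "RegulatorRanking"), is(b, "RegulatorRanking"))
  ta <- a@table; tb <- b@table
  topA <- utils::head(ta$regulator, topN)
  topB <- utils::head(tb$regulator, topN)
  ov <- length(intersect(topA, topB))
  jac <- ov / length(union(topA, topB))
  common <- intersect(ta$regulator, tb$regulator)
  ra <- ta$rank[match(common, ta$regulator)]
  rb <- tb$rank[match(common, tb$regulator)]
  wa <- ta$weightSum[match(common, ta$regulator)]
  wb <- tb$weightSum[match(common, tb$regulator)]
  if (length(common) < 3L) {
    warning("fewer than 3 common regulators; correlations undefined")
    cr <- cw <- NA_real_
  } else {
    cr <- stats::cor(ra, rb)
    cw <- stats::cor(wa, wb)
  }
  list(overlapTopN = ov, jaccardTopN = jac,
       r2Ranks = cr^2, r2WeightSums = cw^2,
       corRanks = cr, corWeightSums = cw, nCommon = length(common))
}
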