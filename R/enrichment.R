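#' Construct a genome-wide background
#'
#' The default size is the Arabidopsis protein-coding gene count (TAIR10,
#' 27416); it is configurable because validation reports must always record
#' the background universe actually used.
#'
#' @param size positive integer population size.
#' @return a [Background-class] of kind \code{"GENOME"}.
#' @export
genomeBackground <- function(size = 27416L) {
  new("Background", kind = "GENOME", size = as.integer(size),
      members = character())
}

#' Construct a microarray probe-set background
#'
#' When experimental targets come from a microarray, both target lists are
#' first intersected with the probed genes and the probe count is the
#' background size.
#'
#' @param members gene ids represented on the array.
#' @return a [Background-class] of kind \code{"PROBESET"}.
#' @export
probesetBackground <- function(members) {
  members <- unique(toupper(members))
  new("Background", kind = "PROBESET", size = length(members),
      members = members)
}

#' Hypergeometric overlap test between in silico and experimental targets
#'
#' Tests whether a regulator's in silico target set overlaps an experimentally
#' determined gene list more than expected by chance, using the upper tail of
#' the hypergeometric distribution (overrepresentation): with population size
#' N (the background), K experimental targets, n in silico targets drawn and k
#' overlapping, the p-value is P(X >= k), computed as the survival function at
#' k - 1. The test is symmetric in which set plays the role of the draws.
#'
#' For a \code{PROBESET} background both sets are first intersected with the
#' probed genes; a set left empty by filtering is an error naming the cause.
#' No multiple-testing correction is applied here; see
#' [validateAgainstExperiments()] for an optional Benjamini-Hochberg column
#' across a report's rows.
#'
#' @param insilico a [TargetSet-class] or character vector of gene ids.
#' @param experimental nonempty character vector of gene ids.
#' @param background a [Background-class].
#' @param label free-text label recorded in the result row.
#' @return one-row data.frame with columns \code{regulator},
#'   \code{n_insilico}, \code{n_experimental}, \code{n_overlap},
#'   \code{background_size}, \code{p_value}, \code{filtered}, \code{label}.
#' @examples
#' bg <- genomeBackground(10)
#' hypergeomOverlap(paste0("G", 1:5), paste0("G", 3:6), bg)
#' @export
hypergeomOverlap <- function(insilico, experimental, background,
                             label = "") {
  stopifnot(is(background, "Background"))
  reg <- NA_character_
  if (is(insilico, "TargetSet")) {
    reg <- insilico@regulator
    insilico <- insilico@targets
  }
  insilico <- unique(toupper(insilico))
  experimental <- unique(toupper(experimental))
  if (!length(experimental)) stop("experimental gene list is empty")
  if (!length(insilico)) stop("in silico target set is empty")
  filtered <- background@kind == "PROBESET"
  if (filtered) {
    insilico <- intersect(insilico, background@members)
    experimental <- intersect(experimental, background@members)
    if (!length(insilico))
      stop("no in silico target is present on the probe set")
    if (!length(experimental))
      stop("no experimental target is present on the probe set")
  }
  N <- background@size
  n <- length(insilico)
  K <- length(experimental)
  if (n > N || K > N)
    stop("background smaller than a target list; check the background spec")
  k <- length(intersect(insilico, experimental))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(regulator = reg, n_insilico = n, n_experimental = K,
             n_overlap = k, background_size = N, p_value = p,
             filtered = filtered, label = label)
}

#' Validate in silico target predictions against experimental lists
#'
#' Runs one hypergeometric overlap test per comparison and assembles a
#' report table (one row per comparison: regulator, counts, p-value, label).
#' Each regulator's in silico target set is retrieved from the network once
#' and reused across its comparisons. An unreadable experimental list produces
#' a per-row error message (column \code{error}); the other rows proceed.
#'
#' @param g a [GRNetwork-class] (typically the trimmed network).
#' @param comparisons list of comparisons, each a list with elements
#'   \code{regulator} (gene id), \code{experimental} (character vector of gene
#'   ids, or a path to a one-id-per-line file), \code{background} (a
#'   [Background-class]) and optionally \code{label}.
#' @param bhCorrect add a Benjamini-Hochberg adjusted p-value column across
#'   the report's rows (off by default; the standard report carries raw
#'   hypergeometric p-values).
#' @return data.frame, one row per comparison.
#' @export
validateAgainstExperiments <- function(g, comparisons, bhCorrect = FALSE) {
  stopifnot(is(g, "GRNetwork"), is.list(comparisons))
  empty <- data.frame(regulator = character(), n_insilico = integer(),
                      n_experimental = integer(), n_overlap = integer(),
                      background_size = integer(), p_value = numeric(),
                      filtered = logical(), label = character(),
                      error = character())
  if (!length(comparisons)) return(empty)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(comparisons, function(cmp) {
    lbl <- if (is.null(cmp$label)) "" else cmp$label
    tryCatch({
      reg <- toupper(cmp$regulator)
      if (!exists(reg, cache))
        assign(reg, getTargets(g, reg), envir = cache)
      ts <- get(reg, cache)
      ex <- cmp$experimental
      # a single string naming a file (or looking like a path) is read as a
      # one-id-per-line gene list; vectors are taken as gene ids directly
      if (is.character(ex) && length(ex) == 1L &&
          (file.exists(ex) || grepl("[/\\\\]|\\.(txt|tsv|gz|list)$", ex)))
        ex <- readGeneList(ex)
      out <- hypergeomOverlap(ts, ex, cmp$background, label = lbl)
      out$error <- NA_character_
      out
    }, error = function(e) {
      data.frame(regulator = toupper(cmp$regulator), n_insilico = NA_integer_,
                 n_experimental = NA_integer_, n_overlap = NA_integer_,
                 background_size = NA_integer_, p_value = NA_real_,
                 filtered = NA, label = lbl, error = conditionMessage(e))
    })
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (bhCorrect)
    res$p_adjust_bh <- stats::p.adjust(res$p_value, method = "BH")
  res
}
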