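.normCategory <- function(x) {
  x <- toupper(trimws(x))
  x[x == "" | is.na(x)] <- "NONE"
  x
}

#' Load a curated regulator list
#'
#' Reads a tab-separated regulator table (columns \code{gene}, \code{symbol},
#' \code{category}; \code{#}-prefixed comment lines skipped) and returns a
#' validated [RegulatorSet-class]. For \code{regClass = "TF"} the category
#' column is ignored and set to \code{"NONE"}; for \code{"EPIGENETIC"} every
#' record must carry one of the four categories (histone modification, DNA
#' methylation, chromatin remodeling, siRNA biogenesis).
#'
#' Gene ids are upper-cased on load (comparison is case-insensitive). Duplicate
#' gene ids, unknown category strings and empty files are errors.
#'
#' @param path path to the TSV file.
#' @param regClass \code{"TF"} or \code{"EPIGENETIC"}.
#' @return a [RegulatorSet-class].
#' @examples
#' epi <- loadRegulators(packagedRegulatorFile("EPIGENETIC"), "EPIGENETIC")
#' countByCategory(epi)
#' @export
loadRegulators <- function(path, regClass = c("EPIGENETIC", "TF")) {
  regClass <- match.arg(regClass)
  if (!file.exists(path)) stop("regulator file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           colClasses = "character", quote = "",
                           fill = FALSE, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty regulator file: ", path)
  need <- c("gene", "symbol", "category")
  if (!all(need %in% names(tab)))
    stop("regulator file must have header columns gene, symbol, category")
  gene <- toupper(trimws(tab$gene))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  category <- if (regClass == "TF") rep("NONE", nrow(tab)) else
    .normCategory(tab$category)
  if (regClass == "EPIGENETIC") {
    bad <- setdiff(unique(category), .EPI_CATEGORIES)
    if (length(bad))
      stop("unknown category value(s): ", paste(bad, collapse = ", "))
  }
  rec <- data.frame(gene = gene, symbol = trimws(tab$symbol),
                    regClass = regClass, category = category,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  new("RegulatorSet", records = rec)
}

#' Combine TF and epigenetic regulator sets into one predictor set
#'
#' Regulator class determines downstream filtering, so a gene present in both
#' inputs is a hard error (naming the offending ids) rather than a silent
#' deduplication.
#'
#' @param ... two or more [RegulatorSet-class] objects.
#' @return a single [RegulatorSet-class].
#' @export
combineRegulatorSets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 2L, all(vapply(sets, is, TRUE, "RegulatorSet")))
  rec <- do.call(rbind, lapply(sets, records))
  dup <- unique(rec$gene[duplicated(rec$gene)])
  if (length(dup))
    stop("gene(s) present in more than one regulator set: ",
         paste(sort(dup), collapse = ", "))
  rec <- rec[order(rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  new("RegulatorSet", records = rec)
}

#' Count epigenetic regulators by functional category
#'
#' @param rs a [RegulatorSet-class].
#' @return named integer vector over the four epigenetic categories; the counts
#'   sum to the number of EPIGENETIC records in \code{rs}.
#' @export
countByCategory <- function(rs) {
  stopifnot(is(rs, "RegulatorSet"))
  epi <- records(rs)
  epi <- epi[epi$regClass == "EPIGENETIC", , drop = FALSE]
  cnt <- table(factor(epi$category, .EPI_CATEGORIES))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Path to a packaged regulator list
#'
#' The package ships synthetic stand-in predictor lists that mirror the curated
#' Arabidopsis resource: 286 epigenetic regulators (174 histone modification,
#' 62 DNA methylation, 30 chromatin remodeling, 20 siRNA) and 1717 TFs. A few
#' literature-anchored entries carry real AGI ids and symbols; the rest are
#' generated placeholders (see the extdata README).
#'
#' @param regClass \code{"EPIGENETIC"} or \code{"TF"}.
#' @return path to the packaged TSV.
#' @export
packagedRegulatorFile <- function(regClass = c("EPIGENETIC", "TF")) {
  regClass <- match.arg(regClass)
  fn <- if (regClass == "EPIGENETIC") "epigenetic_regulators_synthetic.tsv"
        else "tf_regulators_synthetic.tsv"
  system.file("extdata", fn, package = "epigrn", mustWork = TRUE)
}

#' Write a regulator set to TSV
#'
#' Inverse of [loadRegulators()]: \code{loadRegulators(writeRegulators(rs, f))}
#' reproduces \code{rs} for a single-class set.
#'
#' @param rs a [RegulatorSet-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegulators <- function(rs, path) {
  stopifnot(is(rs, "RegulatorSet"))
  rec <- records(rs)
  out <- data.frame(gene = rec$gene, symbol = rec$symbol,
                    category = tolower(rec$category))
  con <- .openOut(path)
  on.exit(close(con))
  writeLines("gene\tsymbol\tcategory", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
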