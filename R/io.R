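.openOut <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

.openIn <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
}

#' Read / write plain gene-list files (one id per line)
#'
#' Blank lines and \code{#} comments are skipped; ids are upper-cased and
#' deduplicated on read.
#'
#' @param path file path (gzip transparently supported by extension).
#' @return character vector of gene ids.
#' @export
readGeneList <- function(path) {
  con <- .openIn(path)
  on.exit(close(con))
  x <- trimws(readLines(con, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty gene list: ", path)
  unique(toupper(x))
}

#' @rdname readGeneList
#' @param genes character vector of gene ids to write.
#' @export
writeGeneList <- function(genes, path) {
  con <- .openOut(path)
  on.exit(close(con))
  writeLines(toupper(genes), con)
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' Format: first column the gene id, header row the sample ids, tab-separated
#' real values.
#'
#' @param path file path.
#' @return numeric genes x samples matrix.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           row.names = 1L, comment.char = "#", quote = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric values in expression matrix: ", path)
  if (anyNA(m)) stop("missing values in expression matrix: ", path)
  rownames(m) <- toupper(rownames(m))
  m
}

#' @rdname readExpressionMatrix
#' @param m numeric matrix with gene rownames and sample colnames.
#' @export
writeExpressionMatrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- .openOut(path)
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list into a network
#'
#' The interchange format mirrors classic inference link lists: three
#' tab-separated columns \code{regulatory_gene}, \code{target_gene},
#' \code{weight} with a header row, sorted by weight descending, weights
#' written with 10 significant digits. Reading validates every row (malformed
#' rows and negative weights are errors naming the line; self-edges violate
#' the network invariant and are rejected).
#'
#' @param path file path (gzip supported by extension).
#' @param regulatorUniverse optional; defaults to the distinct regulators in
#'   the file.
#' @return a [GRNetwork-class].
#' @export
readEdgeList <- function(path, regulatorUniverse = NULL) {
  con <- .openIn(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty edge-list file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("regulatory_gene", "target_gene", "weight")))
    stop("unexpected edge-list header in ", path)
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed edge-list row at line ", bad[1L] + 1L, " of ", path)
  reg <- toupper(vapply(parts, `[[`, "", 1L))
  tgt <- toupper(vapply(parts, `[[`, "", 2L))
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w))
    stop("non-numeric weight at line ", which(is.na(w))[1L] + 1L, " of ", path)
  if (any(w < 0))
    stop("negative weight at line ", which(w < 0)[1L] + 1L, " of ", path)
  if (any(reg == tgt))
    stop("self-edge at line ", which(reg == tgt)[1L] + 1L, " of ", path)
  ed <- data.frame(regulator = reg, target = tgt, weight = w)
  ed <- ed[order(-ed$weight, ed$regulator, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  if (is.null(regulatorUniverse)) regulatorUniverse <- sort(unique(reg))
  new("GRNetwork", edges = ed, regulatorUniverse = toupper(regulatorUniverse))
}

#' @rdname readEdgeList
#' @param g a [GRNetwork-class] to write.
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "GRNetwork"))
  e <- g@edges
  e <- e[order(-e$weight, e$regulator, e$target), , drop = FALSE]
  con <- .openOut(path)
  on.exit(close(con))
  writeLines("regulatory_gene\ttarget_gene\tweight", con)
  if (nrow(e))
    writeLines(paste(e$regulator, e$target,
                     formatC(e$weight, digits = 10, format = "g"),
                     sep = "\t"), con)
  invisible(path)
}

#' Write a regulator ranking as TSV
#'
#' Columns: \code{regulator}, \code{symbol}, \code{class}, \code{weight_sum},
#' \code{rank}, \code{global_rank}.
#'
#' @param r a [RegulatorRanking-class].
#' @param path output path.
#' @export
writeRankingTable <- function(r, path) {
  stopifnot(is(r, "RegulatorRanking"))
  t <- r@table
  out <- data.frame(regulator = t$regulator, symbol = t$symbol,
                    class = ifelse(is.na(t$regClass), "", t$regClass),
                    weight_sum = formatC(t$weightSum, digits = 10,
                                         format = "g"),
                    rank = t$rank, global_rank = t$globalRank)
  con <- .openOut(path)
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulator ranking written by [writeRankingTable()]
#'
#' @param path input path.
#' @param label label for the resulting ranking.
#' @return a [RegulatorRanking-class].
#' @export
readRankingTable <- function(path, label = basename(path)) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           quote = "", comment.char = "#")
  need <- c("regulator", "symbol", "class", "weight_sum", "rank",
            "global_rank")
  if (!all(need %in% names(tab)))
    stop("unexpected ranking header in ", path)
  t <- data.frame(regulator = toupper(tab$regulator), symbol = tab$symbol,
                  regClass = ifelse(nzchar(tab$class), tab$class,
                                    NA_character_),
                  weightSum = as.numeric(tab$weight_sum),
                  rank = as.integer(tab$rank),
                  globalRank = as.integer(tab$global_rank))
  new("RegulatorRanking", table = t, label = label)
}

#' Write the planted edges of a ground-truth network
#'
#' Three tab-separated columns \code{regulatory_gene}, \code{target_gene},
#' \code{effect} (signed).
#'
#' @param net a [TrueNetwork-class].
#' @param path output path.
#' @export
writeTrueEdges <- function(net, path) {
  stopifnot(is(net, "TrueNetwork"))
  con <- .openOut(path)
  on.exit(close(con))
  writeLines("regulatory_gene\ttarget_gene\teffect", con)
  e <- net@edges
  writeLines(paste(e$regulator, e$target,
                   formatC(e$effect, digits = 10, format = "g"), sep = "\t"),
             con)
  invisible(path)
}
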