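#' Run the full inference-to-validation pipeline
#'
#' Executes infer -> trim -> subnetwork -> rank -> (rank-sum when two or more
#' DEG lists are given) -> target retrieval -> (enrichment when comparisons
#' are given), writing each stage's output under \code{outDir} in the
#' package's TSV formats so every artifact is reloadable. Rerunning with an
#' identical configuration reproduces identical files byte for byte. A stage
#' failure aborts with a message naming the stage and the offending input.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised fields:
#'   \describe{
#'     \item{outDir}{output directory (created if needed); required.}
#'     \item{seed}{integer seed; required.}
#'     \item{expression, tfFile, epiFile}{paths to an expression TSV and the
#'       two regulator TSVs; alternatively}
#'     \item{synthetic}{a named list of [syntheticGRNSpec()] arguments — the
#'       benchmark generator then supplies expression, regulators and (with
#'       \code{degContamination}) the DEG list(s).}
#'     \item{degLists}{named list: paths to gene-list files, or character
#'       vectors of gene ids.}
#'     \item{nTrees, kMode, bootstrap}{inference parameters (defaults 1000,
#'       "ALL", TRUE).}
#'     \item{trimFraction}{top-weight fraction retained (default 0.1).}
#'     \item{topN}{truncation depth for rankings and rank-sum (default 25).}
#'     \item{degContamination, nDegLists}{synthetic mode only: contamination
#'       of the generated DEG list(s) (default 0) and how many to draw with
#'       disjoint decoys (default 1).}
#'     \item{comparisons}{list of enrichment comparisons as in
#'       [validateAgainstExperiments()].}
#'   }
#' @return (invisibly) a named list with the objects and file paths produced.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (f in c("outDir", "seed"))
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  paths <- list()
  truth <- NULL

  if (!is.null(config$synthetic)) {
    sim <- stage("simulate", {
      args <- config$synthetic
      args$seed <- seed
      spec <- do.call(syntheticGRNSpec, args)
      truth <- generateTrueNetwork(spec)
      expr <- simulateExpression(truth, spec)
      rs <- regulatorSetFromTruth(truth)
      paths$true_edges <- writeTrueEdges(truth, file.path(outDir,
                                                          "true_edges.tsv"))
      paths$hubs <- writeGeneList(processRegulators(truth),
                                  file.path(outDir, "process_regulators.txt"))
      paths$expression <- writeExpressionMatrix(expr,
                                                file.path(outDir,
                                                          "expression.tsv"))
      list(spec = spec, truth = truth, expr = expr, rs = rs, paths = paths)
    })
    paths <- sim$paths; truth <- sim$truth
    expr <- sim$expr; rs <- sim$rs
    degLists <- config$degLists
    if (is.null(degLists)) {
      nDeg <- if (is.null(config$nDegLists)) 1L else as.integer(config$nDegLists)
      contam <- if (is.null(config$degContamination)) 0 else
        as.numeric(config$degContamination)
      degLists <- list()
      used <- character()
      for (i in seq_len(nDeg)) {
        dl <- makeDegList(truth, contam, seed = seed + i, exclude = used)
        used <- c(used, setdiff(dl, processModule(truth)))
        degLists[[paste0("study", i)]] <- dl
      }
    }
  } else {
    expr <- stage("read-expression", readExpressionMatrix(config$expression))
    rs <- stage("load-regulators", combineRegulatorSets(
      loadRegulators(config$tfFile, "TF"),
      loadRegulators(config$epiFile, "EPIGENETIC")))
    degLists <- config$degLists
  }

  # a length-1 entry is a file path (a DEG list of one gene is meaningless);
  # longer vectors are taken as gene ids directly
  degLists <- lapply(degLists, function(x) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) stop("DEG file not found: ", x)
      readGeneList(x)
    } else toupper(x)
  })

  cfg <- inferenceConfig(
    nTrees = if (is.null(config$nTrees)) 1000L else config$nTrees,
    kMode = if (is.null(config$kMode)) "ALL" else toupper(config$kMode),
    seed = seed,
    bootstrap = if (is.null(config$bootstrap)) TRUE else config$bootstrap)
  grn <- stage("infer", inferNetwork(expr, rs, cfg))
  paths$edges <- writeEdgeList(grn, file.path(outDir, "edges.tsv"))

  frac <- if (is.null(config$trimFraction)) 0.1 else config$trimFraction
  net <- stage("trim", trimTopFraction(grn, frac))
  paths$trimmed <- writeEdgeList(net, file.path(outDir, "trimmed_edges.tsv"))

  topN <- if (is.null(config$topN)) 25L else as.integer(config$topN)
  rankings <- list()
  for (nm in names(degLists)) {
    sub <- stage(paste0("subnet:", nm),
                 extractSubnetwork(net, degLists[[nm]], label = nm))
    paths[[paste0("subnet_", nm)]] <-
      writeEdgeList(sub, file.path(outDir, sprintf("subnet_%s.tsv", nm)))
    rk <- stage(paste0("rank:", nm), rankRegulators(sub, regulators = rs))
    rankings[[nm]] <- rk
    paths[[paste0("ranking_", nm)]] <-
      writeRankingTable(rk, file.path(outDir, sprintf("ranking_%s.tsv", nm)))
  }

  cumulative <- NULL
  if (length(rankings) >= 2L) {
    cumulative <- stage("ranksum", rankSumAggregate(rankings, topN = topN))
    ct <- rankingTable(cumulative)
    p <- file.path(outDir, "cumulative_ranking.tsv")
    utils::write.table(
      data.frame(regulator = ct$regulator, rank_sum = ct$rankSum,
                 cumulative_rank = ct$cumulativeRank,
                 total_weight_sum = formatC(ct$totalWeightSum, digits = 10,
                                            format = "g")),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$cumulative <- p
  }

  targetSet <- NULL
  if (length(rankings)) {
    topReg <- rankingTable(rankings[[1L]])$regulator[1L]
    targetSet <- stage("targets", getTargets(net, topReg))
    paths$targets <- writeGeneList(targets(targetSet),
                                   file.path(outDir, "top_regulator_targets.txt"))
  }

  report <- NULL
  if (!is.null(config$comparisons)) {
    report <- stage("enrich",
                    validateAgainstExperiments(net, config$comparisons))
    p <- file.path(outDir, "enrichment_report.tsv")
    utils::write.table(report, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$enrichment <- p
  }

  prov <- c(sprintf("package: epigrn %s",
                    as.character(utils::packageVersion("epigrn"))),
            sprintf("seed: %d", seed),
            sprintf("trimFraction: %s", format(frac)),
            sprintf("nTrees: %d", cfg@nTrees),
            sprintf("kMode: %s", cfg@kMode),
            sprintf("degLists: %s", paste(names(degLists), collapse = ", ")))
  writeLines(prov, file.path(outDir, "provenance.txt"))
  paths$provenance <- file.path(outDir, "provenance.txt")

  invisible(list(network = grn, trimmed = net, rankings = rankings,
                 cumulative = cumulative, targets = targetSet,
                 enrichment = report, truth = truth, paths = paths))
}
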