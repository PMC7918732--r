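.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

#' Construct a synthetic benchmark specification
#'
#' The defaults describe the package's reference benchmark: 30 TFs and 10
#' epigenetic regulators over 200 targets with mean out-degree 8, three
#' planted process-regulator hubs (at least one epigenetic) driving a module
#' of 30 genes at hub concentration 0.8, absolute linear effects in
#' [0.5, 1.5], Gaussian noise with sd 0.5, and 300 samples.
#'
#' @param nTF,nEpi,nTargets,outDegreeMean,nProcessRegulators,processModuleSize,hubConcentration,effectLow,effectHigh,noiseSD,nSamples,seed
#'   see [SyntheticGRNSpec-class].
#' @return a validated [SyntheticGRNSpec-class].
#' @export
syntheticGRNSpec <- function(nTF = 30, nEpi = 10, nTargets = 200,
                             outDegreeMean = 8, nProcessRegulators = 3,
                             processModuleSize = 30, hubConcentration = 0.8,
                             effectLow = 0.5, effectHigh = 1.5,
                             noiseSD = 0.5, nSamples = 300, seed = 1) {
  new("SyntheticGRNSpec", nTF = as.integer(nTF), nEpi = as.integer(nEpi),
      nTargets = as.integer(nTargets), outDegreeMean = as.numeric(outDegreeMean),
      nProcessRegulators = as.integer(nProcessRegulators),
      processModuleSize = as.integer(processModuleSize),
      hubConcentration = as.numeric(hubConcentration),
      effectLow = as.numeric(effectLow), effectHigh = as.numeric(effectHigh),
      noiseSD = as.numeric(noiseSD), nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' Generate a ground-truth regulator-to-target network
#'
#' Draws an acyclic regulator-to-target graph: regulators occupy the head of a
#' fixed topological order (TFs first, then epigenetic regulators) and may
#' regulate later regulators as well as targets (a cascade), so that
#' "regulator as target" behaviour is exercised. Each regulator receives a
#' Poisson(\code{outDegreeMean}) number of background edges into genes outside
#' the process module. Every process-module gene receives exactly one driver
#' edge; exactly \code{round(hubConcentration * processModuleSize)} of those
#' drivers originate from the planted hub regulators (round-robin), the rest
#' from random non-hub regulators. When epigenetic regulators exist, at least
#' one hub is epigenetic. Effects are drawn uniformly from
#' \eqn{\pm}[\code{effectLow}, \code{effectHigh}]. Generation is a pure
#' function of the spec (including its seed).
#'
#' @param spec a [SyntheticGRNSpec-class].
#' @return a [TrueNetwork-class].
#' @export
generateTrueNetwork <- function(spec) {
  stopifnot(is(spec, "SyntheticGRNSpec"))
  validObject(spec)
  R <- spec@nTF + spec@nEpi
  regs <- sprintf("G%06d", seq_len(R))
  tg <- sprintf("G%06d", R + seq_len(spec@nTargets))
  genes <- c(regs, tg)
  classes <- stats::setNames(rep(c("TF", "EPIGENETIC"), c(spec@nTF, spec@nEpi)),
                             regs)
  .withSeed(spec@seed, {
    hubs <- character()
    if (spec@nProcessRegulators > 0L) {
      epi <- regs[classes == "EPIGENETIC"]
      if (length(epi)) hubs <- sample(epi, 1L)
      pool <- setdiff(regs, hubs)
      extra <- spec@nProcessRegulators - length(hubs)
      if (extra > 0L) hubs <- c(hubs, sample(pool, extra))
      hubs <- sort(hubs)
    }
    module <- sort(sample(tg, spec@processModuleSize))
    # driver edges: one per module gene, hub share fixed by hubConcentration
    drv <- data.frame(regulator = character(), target = character())
    if (length(module)) {
      nHubDrv <- if (length(hubs))
        as.integer(round(spec@hubConcentration * length(module))) else 0L
      who <- sample(module)  # random assignment of module genes to drivers
      hubPart <- who[seq_len(nHubDrv)]
      restPart <- setdiff(who, hubPart)
      nonHub <- setdiff(regs, hubs)
      drvReg <- c(
        if (nHubDrv) rep_len(hubs, nHubDrv),
        if (length(restPart)) {
          src <- if (length(nonHub)) nonHub else regs
          src[1L + (sample.int(length(src), length(restPart),
                               replace = TRUE) - 1L)]
        })
      drv <- data.frame(regulator = drvReg, target = c(hubPart, restPart))
    }
    # background edges: regulator -> later regulators or non-module targets.
    # Both degree distributions are heavy-tailed, as in real regulatory
    # networks: out-degrees are lognormal around the configured mean, and
    # background targets are drawn proportionally to a lognormal gene
    # "popularity", concentrating in-edges on regulatory hotspot genes and
    # leaving many genes without regulators.
    sdlog <- 1.2
    meanlog <- log(spec@outDegreeMean) - sdlog^2 / 2
    degs <- round(stats::rlnorm(R, meanlog, sdlog))
    # only a quarter of genes are responsive to the predictor set at all;
    # among those, popularity is lognormal, so in-edges pile onto hotspots
    popularity <- stats::setNames(
      stats::rlnorm(length(genes), 0, 1.5) *
        (stats::runif(length(genes)) < 0.25), genes)
    bg <- lapply(seq_len(R), function(i) {
      pool <- c(regs[seq_len(R) > i], setdiff(tg, module))
      w <- popularity[pool]
      d <- min(degs[i], sum(w > 0))
      if (!d) return(NULL)
      data.frame(regulator = regs[i],
                 target = sample(pool, d, prob = w))
    })
    ed <- rbind(drv, do.call(rbind, bg))
    ed$effect <- stats::runif(nrow(ed), spec@effectLow, spec@effectHigh) *
      sample(c(-1, 1), nrow(ed), replace = TRUE)
    ed <- ed[order(ed$regulator, ed$target), , drop = FALSE]
    rownames(ed) <- NULL
    new("TrueNetwork", edges = ed, genes = genes,
        regulatorClasses = classes, processRegulators = hubs,
        processModule = module)
  })
}

#' Simulate an expression matrix from a ground-truth network
#'
#' A linear-Gaussian structural model evaluated in topological order: per
#' sample, genes without parents are drawn standard normal; every other gene
#' is the effect-weighted sum of its parents plus Normal(0, noiseSD^2) noise.
#' Reproducible per spec seed (the expression stream is offset from the
#' network stream, so network and matrix are independent draws). In the rare
#' event a gene comes out numerically constant across samples, the matrix is
#' redrawn from the next stream offset (with a message).
#'
#' @param net a [TrueNetwork-class].
#' @param spec the [SyntheticGRNSpec-class] that produced it.
#' @return numeric genes x samples matrix with gene rownames and sample
#'   colnames.
#' @export
simulateExpression <- function(net, spec) {
  stopifnot(is(net, "TrueNetwork"), is(spec, "SyntheticGRNSpec"))
  ed <- net@edges
  genes <- net@genes
  n <- spec@nSamples
  byTarget <- split(ed[c("regulator", "effect")], ed$target)
  draw <- function(offset) .withSeed((spec@seed + offset) %% 2147483629L, {
    m <- matrix(0, length(genes), n,
                dimnames = list(genes, sprintf("S%05d", seq_len(n))))
    for (g in genes) {
      pa <- byTarget[[g]]
      m[g, ] <- if (is.null(pa)) stats::rnorm(n) else
        drop(pa$effect %*% m[pa$regulator, , drop = FALSE]) +
          stats::rnorm(n, 0, spec@noiseSD)
    }
    m
  })
  for (offset in 1:5) {
    m <- draw(offset)
    if (all(.rowVar(m) > 1e-12)) return(m)
    message("constant gene in simulated matrix; redrawing")
  }
  stop("could not simulate a matrix without constant genes")
}

#' Derive a DEG list from the planted process module
#'
#' Emulates a differential-expression study of the planted process: returns
#' the process module with a fraction \code{contamination} of its members
#' replaced by random non-module target genes (decoys). The replaced members
#' are the tail of the module in sorted order, so the retained true core is
#' identical across seeds; the seed controls only the decoy draw.
#'
#' @param net a [TrueNetwork-class] with a nonempty process module.
#' @param contamination fraction in [0, 1) of members replaced by decoys.
#' @param seed integer seed for the decoy draw.
#' @param exclude gene ids never used as decoys (e.g. the decoys of another
#'   list, to make two studies' decoys disjoint).
#' @return sorted character vector of gene ids.
#' @export
makeDegList <- function(net, contamination = 0, seed = 1,
                        exclude = character()) {
  stopifnot(is(net, "TrueNetwork"))
  module <- sort(net@processModule)
  if (!length(module)) stop("network has no process module")
  if (contamination < 0 || contamination >= 1)
    stop("contamination must lie in [0, 1)")
  k <- as.integer(round(contamination * length(module)))
  core <- module[seq_len(length(module) - k)]
  if (!k) return(core)
  tg <- setdiff(net@genes, names(net@regulatorClasses))
  pool <- setdiff(tg, c(module, toupper(exclude)))
  if (length(pool) < k) stop("not enough non-module genes for decoys")
  decoys <- .withSeed(seed, sample(pool, k))
  sort(c(core, decoys))
}

#' Regulator set of a ground-truth network
#'
#' Builds a [RegulatorSet-class] from the generator's regulator classes so the
#' synthetic data can flow through the same inference interface as real data.
#' Epigenetic regulators are assigned the four functional categories in
#' rotation (the generator does not model category-specific behaviour).
#'
#' @param net a [TrueNetwork-class].
#' @return a [RegulatorSet-class].
#' @export
regulatorSetFromTruth <- function(net) {
  stopifnot(is(net, "TrueNetwork"))
  cls <- net@regulatorClasses
  rec <- data.frame(gene = names(cls), symbol = "", regClass = unname(cls),
                    category = "NONE")
  epi <- rec$regClass == "EPIGENETIC"
  rec$category[epi] <- rep_len(.EPI_CATEGORIES, sum(epi))
  rec <- rec[order(rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  new("RegulatorSet", records = rec)
}
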