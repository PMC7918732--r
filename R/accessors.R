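#' @rdname GRNetwork-class
#' @param object,x a package object
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @describeIn GRNetwork-class edge table (regulator, target, weight)
#' @export
setMethod("edges", "GRNetwork", function(x) x@edges)

#' @describeIn TrueNetwork-class planted edge table (regulator, target, effect)
#' @export
setMethod("edges", "TrueNetwork", function(x) x@edges)

#' @rdname GRNetwork-class
#' @export
setGeneric("regulatorUniverse", function(x) standardGeneric("regulatorUniverse"))

#' @describeIn GRNetwork-class the candidate-regulator universe
#' @export
setMethod("regulatorUniverse", "GRNetwork", function(x) x@regulatorUniverse)

#' @rdname RegulatorSet-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @describeIn RegulatorSet-class the record table
#' @export
setMethod("records", "RegulatorSet", function(x) x@records)

#' @rdname RegulatorSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn RegulatorSet-class all gene ids in the set
#' @export
setMethod("geneIds", "RegulatorSet", function(x) x@records$gene)

#' @rdname RegulatorRanking-class
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @describeIn RegulatorRanking-class the ranking as a data.frame
#' @export
setMethod("rankingTable", "RegulatorRanking", function(x) x@table)

#' @describeIn CumulativeRanking-class the cumulative ranking as a data.frame
#' @export
setMethod("rankingTable", "CumulativeRanking", function(x) x@table)

#' @rdname TargetSet-class
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @describeIn TargetSet-class the target gene ids
#' @export
setMethod("targets", "TargetSet", function(x) x@targets)

#' @rdname Subnetwork-class
#' @export
setGeneric("degList", function(x) standardGeneric("degList"))

#' @describeIn Subnetwork-class the DEG list used as target filter
#' @export
setMethod("degList", "Subnetwork", function(x) x@degList)

#' @rdname TrueNetwork-class
#' @export
setGeneric("processRegulators", function(x) standardGeneric("processRegulators"))

#' @describeIn TrueNetwork-class ids of the planted hub regulators
#' @export
setMethod("processRegulators", "TrueNetwork", function(x) x@processRegulators)

#' @rdname TrueNetwork-class
#' @export
setGeneric("processModule", function(x) standardGeneric("processModule"))

#' @describeIn TrueNetwork-class ids of the planted module genes
#' @export
setMethod("processModule", "TrueNetwork", function(x) x@processModule)

#' @rdname TrueNetwork-class
#' @export
setGeneric("regulatorClasses", function(x) standardGeneric("regulatorClasses"))

#' @describeIn TrueNetwork-class named TF/EPIGENETIC class per regulator
#' @export
setMethod("regulatorClasses", "TrueNetwork", function(x) x@regulatorClasses)

setMethod("show", "RegulatorSet", function(object) {
  rec <- object@records
  cat(sprintf("RegulatorSet with %d record(s): %d TF, %d epigenetic\n",
              nrow(rec), sum(rec$regClass == "TF"),
              sum(rec$regClass == "EPIGENETIC")))
  epi <- rec[rec$regClass == "EPIGENETIC", , drop = FALSE]
  if (nrow(epi)) {
    cnt <- table(factor(epi$category, .EPI_CATEGORIES))
    cat("  ", paste(sprintf("%s=%d", tolower(names(cnt)), as.integer(cnt)),
                    collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "GRNetwork", function(object) {
  cat(sprintf("%s: %d edge(s), %d regulator(s) in universe, %d distinct target(s)\n",
              class(object), nrow(object@edges),
              length(object@regulatorUniverse),
              length(unique(object@edges$target))))
  if (is(object, "Subnetwork"))
    cat(sprintf("  parent '%s', DEG list of %d gene(s)\n",
                object@parentLabel, length(object@degList)))
})

setMethod("show", "RegulatorRanking", function(object) {
  cat(sprintf("RegulatorRanking '%s' with %d regulator(s)\n",
              object@label, nrow(object@table)))
  print(utils::head(object@table, 5))
})

setMethod("show", "CumulativeRanking", function(object) {
  cat(sprintf("CumulativeRanking over %d list(s), top %d each; %d regulator(s)\n",
              object@nLists, object@topN, nrow(object@table)))
  print(utils::head(object@table, 5))
})

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet: %d in silico target(s) of %s [%s]\n",
              length(object@targets), object@regulator, object@sourceLabel))
})

setMethod("show", "TrueNetwork", function(object) {
  cat(sprintf(
    "TrueNetwork: %d gene(s), %d planted edge(s), %d hub(s), module of %d\n",
    length(object@genes), nrow(object@edges),
    length(object@processRegulators), length(object@processModule)))
})

setMethod("show", "SyntheticGRNSpec", function(object) {
  cat(sprintf(
    "SyntheticGRNSpec: %d TF + %d epi regulators, %d targets, %d samples (seed %d)\n",
    object@nTF, object@nEpi, object@nTargets, object@nSamples, object@seed))
  cat(sprintf(
    "  out-degree %.1f; %d hub(s), module %d @ concentration %.2f; |beta| in [%.2f, %.2f], noise sd %.2f\n",
    object@outDegreeMean, object@nProcessRegulators, object@processModuleSize,
    object@hubConcentration, object@effectLow, object@effectHigh, object@noiseSD))
})

setMethod("show", "Background", function(object) {
  cat(sprintf("Background (%s), size %d\n", object@kind, object@size))
})
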