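#' Accessors for site-by-sample containers
#'
#' \code{dosage} returns the diploid dosage matrix of a
#' \linkS4class{GenotypeMatrix} or \linkS4class{WorkerSet};
#' \code{alleleFreq} the frequency matrix of a
#' \linkS4class{FrequencyMatrix} or \linkS4class{LineagePanel};
#' \code{poolDepth} the DP matrix of a \linkS4class{PoolCounts};
#' \code{alleleDepth} a list with the \code{ref} and \code{alt} AD matrices;
#' \code{siteIds} the "chrom:pos_ref/alt" site keys; \code{filterLog} the
#' per-stage site/sample accounting accumulated by the filter functions.
#'
#' @param x a package data object.
#' @return the matrix, vector or data.frame described above.
#' @name accessors
#' @examples
#' panel <- simulateLineagePanel(20, seed = 1)
#' head(alleleFreq(panel))
#' head(siteIds(panel))
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setMethod("dosage", "SiteExperiment", function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname accessors
#' @export
setMethod("alleleFreq", "SiteExperiment", function(x) assay(x, "freq"))

#' @rdname accessors
#' @export
setGeneric("poolDepth", function(x) standardGeneric("poolDepth"))

#' @rdname accessors
#' @export
setMethod("poolDepth", "PoolCounts", function(x) assay(x, "dp"))

#' @rdname accessors
#' @export
setGeneric("alleleDepth", function(x) standardGeneric("alleleDepth"))

#' @rdname accessors
#' @export
setMethod("alleleDepth", "PoolCounts", function(x)
  list(ref = assay(x, "adRef"), alt = assay(x, "adAlt")))

#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname accessors
#' @export
setMethod("siteIds", "SiteExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname accessors
#' @export
setMethod("filterLog", "SiteExperiment", function(x) {
  log <- S4Vectors::metadata(x)$filterLog
  if (is.null(log))
    log <- data.frame(stage = character(), sitesIn = integer(),
                      sitesOut = integer(), samplesOut = integer())
  log
})

#' @rdname accessors
#' @export
setGeneric("outgroupFixed", function(x) standardGeneric("outgroupFixed"))

#' @rdname accessors
#' @export
setMethod("outgroupFixed", "LineagePanel",
          function(x) rowData(x)$outgroupFixed)

#' Accessors for admixture fits
#'
#' \code{qMatrix} returns the samples-by-K ancestry membership matrix,
#' \code{fMatrix} the K-by-sites cluster allele-frequency matrix of an
#' \linkS4class{AdmixtureFit}.
#'
#' @param x an \linkS4class{AdmixtureFit}.
#' @return a numeric matrix.
#' @name qMatrix
NULL

#' @rdname qMatrix
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))

#' @rdname qMatrix
#' @export
setMethod("qMatrix", "AdmixtureFit", function(x) x@Q)

#' @rdname qMatrix
#' @export
setGeneric("fMatrix", function(x) standardGeneric("fMatrix"))

#' @rdname qMatrix
#' @export
setMethod("fMatrix", "AdmixtureFit", function(x) x@F)

setMethod("show", "ColonySpec", function(object) {
  cat("ColonySpec: queen C-ancestry ", format(object@queenAncestry),
      ", ", length(object@droneAncestries), " drone mate(s), ",
      object@nWorkersPool, " workers pooled, donor ", object@donorLineage,
      "\n", sep = "")
})

setMethod("show", "LineagePanel", function(object) {
  cat("LineagePanel with ", nrow(object), " sites (",
      sum(rowData(object)$outgroupFixed), " outgroup-fixed)\n", sep = "")
  callNextMethod()
})

setMethod("show", "TrioResult", function(object) {
  cat("ABBA BABA test [P1=", object@populations[["P1"]],
      ", P2=", object@populations[["P2"]],
      ", P3=", object@populations[["P3"]], "]\n", sep = "")
  cat(sprintf("  D = %.4f  (jackknife SE %.4f, %d blocks, %d sites)\n",
              object@D, object@jackknifeSE, object@nBlocks, object@nSites))
  cat(sprintf("  Z = %.3f, two-sided p = %.3g\n", object@Z, object@pValue))
  if (!is.na(object@f))
    cat(sprintf("  f admixture proportion = %.4f\n", object@f))
})

setMethod("show", "BatterySummary", function(object) {
  cat("Trio battery for focal colony '", object@focal, "': ",
      nrow(object@tests), " tests\n", sep = "")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel (Q >= ", object@threshold, "):\n", sep = "")
  for (g in names(object@groups))
    cat("  ", g, ": ", length(object@groups[[g]]), " colonies\n", sep = "")
})

setMethod("show", "AdmixtureFit", function(object) {
  cat("AdmixtureFit: K = ", object@K, ", ", nrow(object@Q), " samples, ",
      ncol(object@F), " sites\n", sep = "")
  cat(sprintf("  final log-likelihood %.3f after %d iterations (%s)\n",
              object@logLik[length(object@logLik)], length(object@logLik),
              if (object@converged) "converged" else "max iterations"))
  if (length(object@supervised))
    cat("  supervised samples:", length(object@supervised), "\n")
})

setMethod("show", "AdmixtureCV", function(object) {
  cat("Cross-validation over K:\n")
  print(round(object@error, 5))
  cat("chosen K =", object@chosenK, "\n")
})
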