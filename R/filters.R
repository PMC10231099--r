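#' Site and sample quality filters
#'
#' The filters mirror the quality-control sequence applied to RAD-seq variant
#' matrices before introgression analysis, in the fixed order biallelic ->
#' depth -> site missingness -> sample missingness -> intersection.  Every
#' filter is idempotent, never adds sites or samples, and appends a row to
#' the object's [filterLog()] recording sites in/out and samples retained.
#' Missingness is defined as \code{NA} dosage for individuals and zero depth
#' for pools; thresholds are inclusive (a site observed in exactly the
#' threshold fraction of samples is kept).
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{PoolCounts}.
#' @param minDepth minimum per-site mean depth (default 5).
#' @param maxRule \code{"double-mean"} removes sites whose mean depth exceeds
#'   twice the grand mean depth over all sites; \code{"fixed"} uses
#'   \code{maxDepth}.
#' @param maxDepth depth ceiling when \code{maxRule = "fixed"}.
#' @param threshold inclusive missingness threshold in (0, 1] (default 0.9).
#' @return the filtered object, of the same class.
#' @name filters
#' @examples
#' panel <- simulateLineagePanel(60, seed = 1)
#' ws <- simulateColony(ColonySpec(0, 0), panel, seed = 2)
#' pc <- sequencePool(ws, 40, seed = 3)
#' pc <- filterDepth(pc)
#' filterLog(pc)
NULL

.missingMask <- function(x) {
  if (is(x, "PoolCounts")) poolDepth(x) == 0L else is.na(dosage(x))
}

#' @rdname filters
#' @export
filterBiallelic <- function(x) {
  stopifnot(is(x, "SiteExperiment"))
  ok <- !grepl(",", rowData(x)$alt) & !grepl(",", rowData(x)$ref) &
    rowData(x)$alt != "." & nchar(rowData(x)$alt) > 0L
  out <- x[ok, ]
  .logStage(out, "biallelic", nrow(x), nrow(out), ncol(out))
}

#' @rdname filters
#' @export
filterDepth <- function(x, minDepth = 5, maxRule = c("double-mean", "fixed"),
                        maxDepth = NULL) {
  stopifnot(is(x, "SiteExperiment"))
  maxRule <- match.arg(maxRule)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("cannot depth-filter an empty matrix")
  if (is(x, "PoolCounts")) {
    dp <- poolDepth(x)
  } else if ("dp" %in% assayNames(x)) {
    dp <- assay(x, "dp")
  } else {
    stop("no per-site depth available on this object")
  }
  siteMean <- rowMeans(dp, na.rm = TRUE)
  ceiling <- switch(maxRule,
    "double-mean" = 2 * mean(siteMean),
    "fixed" = {
      if (is.null(maxDepth)) stop("maxDepth required for the fixed rule")
      maxDepth
    })
  ok <- siteMean >= minDepth & siteMean <= ceiling
  out <- x[ok, ]
  .logStage(out, sprintf("depth[%g,%g]", minDepth, ceiling),
            nrow(x), nrow(out), ncol(out))
}

#' @rdname filters
#' @export
filterSiteMissingness <- function(x, threshold = 0.9) {
  stopifnot(is(x, "SiteExperiment"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (ncol(x) == 0L) return(.logStage(x, "siteMissingness", nrow(x),
                                      nrow(x), 0L))
  present <- rowMeans(!.missingMask(x))
  out <- x[present >= threshold, ]
  .logStage(out, "siteMissingness", nrow(x), nrow(out), ncol(out))
}

#' @rdname filters
#' @export
filterSampleMissingness <- function(x, threshold = 0.9) {
  stopifnot(is(x, "SiteExperiment"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  present <- colMeans(!.missingMask(x))
  keep <- present >= threshold
  if (any(!keep))
    message("dropping sample(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  out <- x[, keep]
  .logStage(out, "sampleMissingness", nrow(x), nrow(out), ncol(out))
}

#' Restrict two matrices to their shared sites
#'
#' Restricts both inputs to the exact intersection of sites, where site
#' identity is the (chromosome, position, REF, ALT) tuple — not position
#' alone — so that records whose alleles disagree between datasets are
#' dropped (with a warning) rather than silently matched.  Output order
#' follows the first input.
#'
#' @param a,b site-by-sample containers sharing a coordinate convention.
#' @return a list with elements \code{a} and \code{b}, both restricted to the
#'   common sites in the same order.
#' @examples
#' panel <- simulateLineagePanel(30, seed = 1)
#' ws <- simulateColony(ColonySpec(0, 0), panel, seed = 2)
#' pc <- sequencePool(ws, 40, seed = 3)
#' both <- intersectSites(pc, pc[1:10, ])
#' nrow(both$a)
#' @export
intersectSites <- function(a, b) {
  stopifnot(is(a, "SiteExperiment"), is(b, "SiteExperiment"))
  shared <- intersect(siteIds(a), siteIds(b))
  posKey <- function(x) sub("_.*$", "", siteIds(x))
  posShared <- intersect(posKey(a), posKey(b))
  if (length(posShared) > length(shared))
    warning(length(posShared) - length(shared),
            " position-matched site(s) dropped for mismatched alleles")
  if (length(shared) == 0L)
    stop("no sites shared between the two matrices")
  outA <- a[match(shared, siteIds(a)), ]
  outB <- b[match(shared, siteIds(b)), ]
  list(a = .logStage(outA, "intersect", nrow(a), nrow(outA), ncol(outA)),
       b = .logStage(outB, "intersect", nrow(b), nrow(outB), ncol(outB)))
}

#' Estimate pooled allele frequencies from AD/DP read counts
#'
#' Per site and pooled sample, the derived (alternate) allele frequency is
#' the alternate supporting-read count divided by total depth, the standard
#' pool-seq estimator for equimolar pools.  Sites with zero depth are
#' missing, never zero.  Records whose AD fields do not sum to DP raise an
#' error naming the first offending record.
#'
#' @param pool a \linkS4class{PoolCounts}.
#' @return a \linkS4class{FrequencyMatrix} with the same sites and samples.
#' @examples
#' pc <- PoolCounts(adRef = matrix(10L), adAlt = matrix(30L),
#'                  dp = matrix(40L), chrom = "1", pos = 1L,
#'                  ref = "A", alt = "T", sampleIds = "pool1")
#' alleleFreq(estimatePoolFrequencies(pc))  # 0.75
#' @export
estimatePoolFrequencies <- function(pool) {
  stopifnot(is(pool, "PoolCounts"))
  ad <- alleleDepth(pool)
  dp <- poolDepth(pool)
  bad <- which(ad$ref + ad$alt != dp, arr.ind = TRUE)
  if (nrow(bad))
    stop("AD fields do not sum to DP at record ",
         siteIds(pool)[bad[1L, 1L]], " sample ",
         colnames(pool)[bad[1L, 2L]])
  f <- ad$alt / dp
  f[dp == 0L] <- NA_real_
  out <- .newSiteExperiment("FrequencyMatrix", list(freq = f),
                            rowRanges(pool), colnames(pool),
                            metadata = S4Vectors::metadata(pool))
  out
}
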