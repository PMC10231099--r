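#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols "metadata<-" "mcols<-"
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowRanges colData assayNames "assay<-"
#' @importFrom BiocGenerics start
#' @importFrom stats pnorm rbeta rbinom rpois runif rgamma sd cor complete.cases
#' @importFrom utils read.delim head
NULL

#' Site-by-sample experiment containers
#'
#' All site-by-sample data in the package are held in lightweight extensions
#' of \linkS4class{RangedSummarizedExperiment}: rows are biallelic SNP sites
#' (a \code{GRanges} with \code{ref}/\code{alt} alleles in its metadata
#' columns), columns are samples.  Three concrete classes are used:
#' \describe{
#'   \item{\code{PoolCounts}}{assays \code{adRef}, \code{adAlt}, \code{dp}:
#'     per-site supporting-read counts for the reference and alternate allele
#'     (the VCF AD field) and total depth (DP) of a pooled sample.}
#'   \item{\code{GenotypeMatrix}}{assay \code{dosage}: diploid derived-allele
#'     dosage in \{0, 1, 2\}, \code{NA} for missing.}
#'   \item{\code{FrequencyMatrix}}{assay \code{freq}: derived/alternate allele
#'     frequency in [0, 1], \code{NA} for missing.}
#' }
#'
#' @name SiteExperiment-class
#' @aliases PoolCounts-class GenotypeMatrix-class FrequencyMatrix-class
#' @exportClass SiteExperiment PoolCounts GenotypeMatrix FrequencyMatrix
setClass("SiteExperiment",
  contains = c("RangedSummarizedExperiment", "VIRTUAL"))

setClass("PoolCounts", contains = "SiteExperiment")

setClass("GenotypeMatrix", contains = "SiteExperiment")

setClass("FrequencyMatrix", contains = "SiteExperiment")

.validSites <- function(object) {
  msg <- NULL
  rd <- rowData(object)
  if (!all(c("ref", "alt") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry 'ref' and 'alt' allele columns")
  msg
}

setValidity("PoolCounts", function(object) {
  msg <- .validSites(object)
  need <- c("adRef", "adAlt", "dp")
  if (!all(need %in% assayNames(object)))
    return(c(msg, "assays 'adRef', 'adAlt', 'dp' are required"))
  ar <- assay(object, "adRef"); aa <- assay(object, "adAlt")
  dp <- assay(object, "dp")
  if (any(ar < 0, na.rm = TRUE) || any(aa < 0, na.rm = TRUE) ||
      any(dp < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be nonnegative")
  bad <- which(ar + aa != dp)
  if (length(bad))
    msg <- c(msg, sprintf("adRef + adAlt != dp at %d record(s), first: %s",
                          length(bad), rownames(object)[bad[1L]]))
  if (is.null(msg)) TRUE else msg
})

setValidity("GenotypeMatrix", function(object) {
  msg <- .validSites(object)
  if (!"dosage" %in% assayNames(object))
    return(c(msg, "assay 'dosage' is required"))
  g <- assay(object, "dosage")
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (is.null(msg)) TRUE else msg
})

setValidity("FrequencyMatrix", function(object) {
  msg <- .validSites(object)
  if (!"freq" %in% assayNames(object))
    return(c(msg, "assay 'freq' is required"))
  f <- assay(object, "freq")
  if (any(f < 0 | f > 1, na.rm = TRUE))
    msg <- c(msg, "frequencies must lie in [0, 1] or be NA")
  if (is.null(msg)) TRUE else msg
})

#' Lineage allele-frequency panel
#'
#' Per-site derived-allele frequencies for the two diverged in-group lineages
#' (M and C, the latter split into subpopulations C1 and C2 emulating
#' \emph{A. m. carnica} and \emph{A. m. ligustica}) and an outgroup.  Rows are
#' sites, columns are the four populations \code{M}, \code{C1}, \code{C2},
#' \code{outgroup}.  \code{rowData(panel)$outgroupFixed} flags the sites at
#' which the outgroup is fixed for the ancestral allele (frequency exactly 0);
#' only such sites enter ABBA BABA analyses.  \code{metadata(panel)} records
#' the drift parameters and seed used by the generator.
#'
#' @name LineagePanel-class
#' @seealso [simulateLineagePanel()]
#' @exportClass LineagePanel
setClass("LineagePanel", contains = "SiteExperiment")

setValidity("LineagePanel", function(object) {
  msg <- .validSites(object)
  if (!"freq" %in% assayNames(object))
    return(c(msg, "assay 'freq' is required"))
  f <- assay(object, "freq")
  if (!identical(colnames(f), c("M", "C1", "C2", "outgroup")))
    msg <- c(msg, "columns must be 'M', 'C1', 'C2', 'outgroup'")
  if (any(f < 0 | f > 1, na.rm = TRUE))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  fx <- rowData(object)$outgroupFixed
  if (is.null(fx)) {
    msg <- c(msg, "rowData must carry logical 'outgroupFixed'")
  } else if ("outgroup" %in% colnames(f)) {
    og <- f[, "outgroup"]
    if (any(fx & og != 0 & og != 1))
      msg <- c(msg, "outgroup-fixed sites must have outgroup frequency 0 or 1")
  }
  if (any(duplicated(rownames(object))))
    msg <- c(msg, "site ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Specification of one polyandrous colony
#'
#' Describes the queen and her mates for the haplodiploid colony simulator:
#' the proportion of C-lineage ancestry in the queen's genome, one such
#' proportion per (haploid) drone mate, the number of workers pooled for
#' sequencing, and the patriline weights (expected offspring share per drone).
#'
#' @slot queenAncestry numeric in [0, 1]; C-lineage proportion of the queen.
#' @slot droneAncestries numeric vector in [0, 1], one entry per drone mate.
#' @slot nWorkersPool positive integer; workers sampled into the pool.
#' @slot patrilineWeights nonnegative weights summing to 1, one per drone.
#' @slot donorLineage which C subpopulation of the panel supplies C alleles
#'   (\code{"C1"} or \code{"C2"}).
#'
#' @seealso [ColonySpec()], [simulateColony()]
#' @exportClass ColonySpec
setClass("ColonySpec", representation(
  queenAncestry    = "numeric",
  droneAncestries  = "numeric",
  nWorkersPool     = "integer",
  patrilineWeights = "numeric",
  donorLineage     = "character"))

setValidity("ColonySpec", function(object) {
  msg <- NULL
  if (length(object@queenAncestry) != 1L ||
      object@queenAncestry < 0 || object@queenAncestry > 1)
    msg <- c(msg, "queenAncestry must be a single value in [0, 1]")
  if (length(object@droneAncestries) < 1L)
    msg <- c(msg, "at least one drone mate is required")
  if (any(object@droneAncestries < 0 | object@droneAncestries > 1))
    msg <- c(msg, "droneAncestries must lie in [0, 1]")
  if (object@nWorkersPool < 1L)
    msg <- c(msg, "nWorkersPool must be positive")
  w <- object@patrilineWeights
  if (length(w) != length(object@droneAncestries))
    msg <- c(msg, "one patriline weight per drone is required")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "patrilineWeights must be nonnegative and sum to 1")
  if (!object@donorLineage %in% c("C1", "C2"))
    msg <- c(msg, "donorLineage must be 'C1' or 'C2'")
  if (is.null(msg)) TRUE else msg
})

#' Realized workers of one simulated colony
#'
#' Holds the diploid workers of one colony: assays \code{dosage} (derived
#' allele count in \{0, 1, 2\}), \code{maternal} and \code{paternal} (the two
#' binary parental haplotypes, whose sum is the dosage at every site).
#' \code{colData(x)$patriline} records each worker's drone of origin, so that
#' patriline structure is available downstream.
#'
#' @name WorkerSet-class
#' @seealso [simulateColony()]
#' @exportClass WorkerSet
setClass("WorkerSet", contains = "SiteExperiment")

setValidity("WorkerSet", function(object) {
  msg <- .validSites(object)
  need <- c("dosage", "maternal", "paternal")
  if (!all(need %in% assayNames(object)))
    return(c(msg, "assays 'dosage', 'maternal', 'paternal' are required"))
  g <- assay(object, "dosage")
  if (!all(g == assay(object, "maternal") + assay(object, "paternal")))
    msg <- c(msg, "dosage must equal maternal + paternal at every site")
  pl <- colData(object)$patriline
  if (is.null(pl))
    msg <- c(msg, "colData must carry 'patriline'")
  if (is.null(msg)) TRUE else msg
})

#' Polarized site frequencies for one four-taxon test
#'
#' Per-site derived-allele frequencies for the three in-group populations of
#' an ABBA BABA test, restricted to sites at which the outgroup is fixed for
#' the ancestral allele (so the outgroup frequency is 0 by construction).  An
#' optional second donor-lineage representative \code{p3a} supports the f
#' admixture-proportion estimator.  \code{blockId} assigns each site to one of
#' the contiguous, equal-SNP-count jackknife blocks.
#'
#' @slot p1,p2,p3 numeric per-site frequencies in [0, 1].
#' @slot p3a numeric; second donor representative (length 0 if absent).
#' @slot blockId integer block assignment per site.
#' @slot siteId character site labels.
#' @slot nDropped integer; sites removed for missing frequencies.
#'
#' @seealso [makeTrio()], [pattersonD()], [blockJackknife()]
#' @exportClass PolarizedTrio
setClass("PolarizedTrio", representation(
  p1 = "numeric", p2 = "numeric", p3 = "numeric", p3a = "numeric",
  blockId = "integer", siteId = "character", nDropped = "integer"))

setValidity("PolarizedTrio", function(object) {
  msg <- NULL
  n <- length(object@p1)
  if (length(object@p2) != n || length(object@p3) != n)
    msg <- c(msg, "p1, p2, p3 must have equal length")
  if (length(object@p3a) && length(object@p3a) != n)
    msg <- c(msg, "p3a must be empty or match p1 in length")
  if (length(object@blockId) != n)
    msg <- c(msg, "blockId must match site count")
  for (s in c("p1", "p2", "p3", "p3a")) {
    v <- slot(object, s)
    if (length(v) && any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (is.null(msg)) TRUE else msg
})

#' Result of one ABBA BABA test
#'
#' Pattern sums, Patterson's D with block-jackknife standard error, Z score
#' and two-sided p-value, plus (when a second donor representative is
#' available) the f admixture-proportion estimate, for a single
#' (P1, P2, P3, outgroup) test.
#'
#' @slot populations named character vector of population labels.
#' @slot abbaSum,babaSum weighted ABBA / BABA pattern sums.
#' @slot D Patterson's D in [-1, 1].
#' @slot jackknifeSE,Z,pValue delete-one-block jackknife standard error,
#'   Z = D / SE, and two-sided normal p-value.
#' @slot f f admixture proportion (NA when no second donor representative).
#' @slot nSites,nBlocks sites and jackknife blocks used.
#'
#' @seealso [dstatTest()]
#' @exportClass TrioResult
setClass("TrioResult", representation(
  populations = "character",
  abbaSum = "numeric", babaSum = "numeric", D = "numeric",
  jackknifeSE = "numeric", Z = "numeric", pValue = "numeric",
  f = "numeric", nSites = "integer", nBlocks = "integer"))

#' Reference colony panel for the trio battery
#'
#' Reference colonies grouped by subspecies label, each having shown an
#' ancestry membership (Q) to its own cluster at or above the selection
#' threshold, so that panels contain only colonies with low or no
#' introgression.
#'
#' @slot groups named list of character vectors of colony ids per subspecies.
#' @slot qTable the (colony, subspecies, q) table the panel was built from.
#' @slot threshold the Q selection threshold applied.
#'
#' @seealso [selectReferenceColonies()], [enumerateTrios()]
#' @exportClass ReferencePanel
setClass("ReferencePanel", representation(
  groups = "list", qTable = "data.frame", threshold = "numeric"))

#' Aggregated trio battery for one focal colony
#'
#' All ABBA BABA tests of one focal colony against every combination of
#' reference colonies, with per-donor-subspecies aggregation (mean and SD of
#' f, test counts) and the all-combinations significance classification.
#'
#' @slot focal focal colony id.
#' @slot tests per-test data.frame (p1, p3, p3a, donor, D, Z, pValue, f).
#' @slot summary per-donor data.frame (donor, meanF, sdF, nTests, class).
#' @slot nBlocks jackknife blocks used per test.
#' @slot alpha significance level of the classification.
#'
#' @seealso [runBattery()]
#' @exportClass BatterySummary
setClass("BatterySummary", representation(
  focal = "character", tests = "data.frame", summary = "data.frame",
  nBlocks = "integer", alpha = "numeric"))

#' Maximum-likelihood admixture fit
#'
#' Ancestry membership proportions Q (samples x K, rows on the simplex) and
#' cluster allele frequencies F (K x sites, clamped to [eps, 1-eps]) maximizing
#' the binomial admixture likelihood, together with the log-likelihood trace
#' of the EM iterations.
#'
#' @slot Q numeric samples-by-K membership matrix.
#' @slot F numeric K-by-sites cluster frequency matrix.
#' @slot logLik log-likelihood value per EM iteration (last = final).
#' @slot K integer number of clusters.
#' @slot converged logical; TRUE if the tolerance was reached before maxIter.
#' @slot supervised character ids of samples with fixed Q rows.
#'
#' @seealso [fitAdmixture()], [qMatrix()], [fMatrix()]
#' @exportClass AdmixtureFit
setClass("AdmixtureFit", representation(
  Q = "matrix", F = "matrix", logLik = "numeric", K = "integer",
  converged = "logical", supervised = "character"))

setValidity("AdmixtureFit", function(object) {
  msg <- NULL
  if (nrow(object@Q) && any(abs(rowSums(object@Q) - 1) > 1e-8))
    msg <- c(msg, "Q rows must sum to 1 within 1e-8")
  if (any(object@Q < 0))
    msg <- c(msg, "Q must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Cross-validation over candidate cluster numbers
#'
#' Masked-entry cross-validation error per candidate K; the most likely K is
#' the one attaining the minimum error.
#'
#' @slot error named numeric vector of CV errors, one per K.
#' @slot chosenK integer; K attaining the minimum.
#' @slot nFolds,maskFraction the CV design used.
#'
#' @seealso [crossValidation()]
#' @exportClass AdmixtureCV
setClass("AdmixtureCV", representation(
  error = "numeric", chosenK = "integer",
  nFolds = "integer", maskFraction = "numeric"))

setValidity("AdmixtureCV", function(object) {
  if (length(object@error) &&
      object@error[as.character(object@chosenK)] > min(object@error) + 1e-12)
    "chosenK must attain the minimum CV error" else TRUE
})
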