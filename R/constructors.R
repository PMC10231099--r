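# Internal: evaluate code under a local, restored RNG state when a seed is
# given; with seed = NULL the global RNG stream is used as-is.
.withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Internal: build the GRanges row scaffold shared by all site containers.
.siteRanges <- function(chrom, pos, ref, alt) {
  gr <- GRanges(chrom, IRanges(start = pos, width = 1L))
  S4Vectors::mcols(gr)$ref <- ref
  S4Vectors::mcols(gr)$alt <- alt
  names(gr) <- paste0(chrom, ":", pos, "_", ref, "/", alt)
  gr
}

.newSiteExperiment <- function(class, assays, sites, sampleIds,
                               colData = NULL, metadata = list()) {
  assays <- lapply(assays, function(a) {
    a <- as.matrix(a)
    dimnames(a) <- list(names(sites), sampleIds)
    a
  })
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = sampleIds)
  se <- SummarizedExperiment(assays = assays, rowRanges = sites,
                             colData = colData, metadata = metadata)
  out <- as(se, class)
  validObject(out)
  out
}

#' Construct site-by-sample containers from raw matrices
#'
#' Build a \linkS4class{GenotypeMatrix}, \linkS4class{PoolCounts} or
#' \linkS4class{FrequencyMatrix} from plain matrices plus site coordinates.
#' Sites are keyed by chromosome, 1-based position and the REF/ALT allele
#' pair, the identity used by [intersectSites()].
#'
#' @param dosage integer matrix (sites x samples) of diploid dosages in
#'   \{0, 1, 2\}, \code{NA} for missing.
#' @param adRef,adAlt,dp integer matrices (sites x samples) of supporting-read
#'   counts; \code{adRef + adAlt} must equal \code{dp} everywhere.
#' @param freq numeric matrix (sites x samples) of allele frequencies.
#' @param chrom,pos,ref,alt per-site coordinates and alleles.
#' @param sampleIds sample (column) names.
#' @return an object of the corresponding class.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 1L), 2),
#'                      chrom = c("1", "1"), pos = c(10L, 20L),
#'                      ref = c("A", "G"), alt = c("T", "C"),
#'                      sampleIds = c("w1", "w2"))
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, ref, alt,
                           sampleIds = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(dosage)))
  .newSiteExperiment("GenotypeMatrix", list(dosage = dosage),
                     .siteRanges(chrom, pos, ref, alt), sampleIds)
}

#' @rdname GenotypeMatrix
#' @export
PoolCounts <- function(adRef, adAlt, dp, chrom, pos, ref, alt,
                       sampleIds = colnames(dp)) {
  if (is.null(sampleIds))
    sampleIds <- paste0("pool", seq_len(ncol(as.matrix(dp))))
  .newSiteExperiment("PoolCounts",
                     list(adRef = adRef, adAlt = adAlt, dp = dp),
                     .siteRanges(chrom, pos, ref, alt), sampleIds)
}

#' @rdname GenotypeMatrix
#' @export
FrequencyMatrix <- function(freq, chrom, pos, ref, alt,
                            sampleIds = colnames(freq)) {
  if (is.null(sampleIds))
    sampleIds <- paste0("sample", seq_len(ncol(as.matrix(freq))))
  .newSiteExperiment("FrequencyMatrix", list(freq = freq),
                     .siteRanges(chrom, pos, ref, alt), sampleIds)
}

#' Specify a polyandrous colony
#'
#' @param queenAncestry C-lineage ancestry proportion of the queen, in [0, 1].
#' @param droneAncestries numeric vector of C-lineage proportions, one per
#'   drone mate.  Queens mate with many drones; the number of mates is left
#'   free because it varies widely between populations.
#' @param nWorkersPool number of workers sampled into the colony pool
#'   (default 30, the usual pool size for colony pool-seq).
#' @param patrilineWeights expected offspring proportion per drone; defaults
#'   to uniform.  Skewed weights probe how unrepresentative a single worker
#'   can be.
#' @param donorLineage which C subpopulation of the panel supplies C alleles.
#' @return a \linkS4class{ColonySpec}.
#' @examples
#' ColonySpec(0.25, droneAncestries = rep(c(0, 1), c(6, 2)))
#' @export
ColonySpec <- function(queenAncestry, droneAncestries, nWorkersPool = 30L,
                       patrilineWeights = NULL, donorLineage = "C1") {
  if (length(droneAncestries) == 0L)
    stop("at least one drone mate is required")
  if (is.null(patrilineWeights))
    patrilineWeights <- rep(1 / length(droneAncestries),
                            length(droneAncestries))
  new("ColonySpec", queenAncestry = queenAncestry,
      droneAncestries = as.numeric(droneAncestries),
      nWorkersPool = as.integer(nWorkersPool),
      patrilineWeights = as.numeric(patrilineWeights),
      donorLineage = donorLineage)
}

# Internal: append one row to the filter log carried in metadata().
.logStage <- function(x, stage, sitesIn, sitesOut, samplesOut) {
  log <- filterLog(x)
  S4Vectors::metadata(x)$filterLog <- rbind(
    log, data.frame(stage = stage, sitesIn = sitesIn,
                    sitesOut = sitesOut, samplesOut = samplesOut))
  x
}
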