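#' Balding-Nichols drift of allele frequencies
#'
#' Draws descendant population frequencies from a Beta distribution centred on
#' the ancestral frequency \code{p} with an FST-like drift parameter
#' \code{fst}: \code{Beta(p (1-F)/F, (1-p)(1-F)/F)}.  Under this model two
#' populations drifted independently with parameter \code{F} from a shared
#' ancestor have expected Hudson FST approximately \code{F}.  \code{fst = 0}
#' returns \code{p} unchanged; frequencies of exactly 0 or 1 are absorbing.
#'
#' @param p numeric vector of ancestral frequencies in [0, 1].
#' @param fst drift parameter in [0, 1).
#' @return numeric vector of drifted frequencies, one per input site.
#' @examples
#' withr::with_seed(1, driftFrequencies(rep(0.5, 5), 0.2))
#' @export
driftFrequencies <- function(p, fst) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (fst == 0) return(p)
  out <- p
  mid <- p > 0 & p < 1
  k <- (1 - fst) / fst
  out[mid] <- rbeta(sum(mid), p[mid] * k, (1 - p[mid]) * k)
  out
}

#' Simulate a lineage allele-frequency panel
#'
#' Generates per-site derived-allele frequencies for two diverged in-group
#' lineages M and C (C split into subpopulations C1 and C2) and an outgroup,
#' emulating the population structure of C-lineage introgression studies in
#' \emph{Apis mellifera mellifera}: an ancestral frequency is drawn uniformly
#' on [0.05, 0.95] per site, then each lineage drifts from it under a
#' Balding-Nichols model.  A stated fraction of sites is flagged
#' "outgroup-fixed": there the outgroup carries the ancestral allele at
#' frequency exactly 0, defining the ancestral state for ABBA BABA
#' polarization.  Sites are laid out 1-based and sorted along
#' \code{nChromosomes} synthetic chromosomes so that contiguous jackknife
#' blocks span contig boundaries.
#'
#' @param nSites number of biallelic sites (>= 1).
#' @param divergence named numeric drift parameters, all > 0 unless stated:
#'   \code{MC} applied independently to the M and the C branch (so Hudson
#'   FST(M, C) is approximately \code{MC}); \code{C12} applied to each of C1
#'   and C2 below the C ancestor (0 allowed and collapses C1 and C2);
#'   \code{outgroup} drifts the outgroup at sites not flagged fixed.
#' @param outgroupFixedFraction fraction of sites at which the outgroup is
#'   fixed for the ancestral allele.
#' @param nChromosomes number of synthetic chromosomes (default 2).
#' @param seed integer seed; recorded in \code{metadata()} of the result.
#' @return a \linkS4class{LineagePanel}.
#' @examples
#' panel <- simulateLineagePanel(100, seed = 7)
#' panel
#' @export
simulateLineagePanel <- function(nSites,
                                 divergence = c(MC = 0.30, C12 = 0.05,
                                                outgroup = 0.50),
                                 outgroupFixedFraction = 0.8,
                                 nChromosomes = 2L, seed = NULL) {
  if (nSites < 1) stop("nSites must be positive")
  divergence <- divergence[c("MC", "C12", "outgroup")]
  if (anyNA(divergence))
    stop("divergence must name 'MC', 'C12' and 'outgroup'")
  if (divergence[["MC"]] <= 0 || divergence[["outgroup"]] <= 0 ||
      divergence[["C12"]] < 0)
    stop("divergence parameters must be positive (C12 may be 0)")
  if (outgroupFixedFraction < 0 || outgroupFixedFraction > 1)
    stop("outgroupFixedFraction must lie in [0, 1]")
  .withSeed(seed, {
    pAnc <- runif(nSites, 0.05, 0.95)
    fM  <- driftFrequencies(pAnc, divergence[["MC"]])
    pC  <- driftFrequencies(pAnc, divergence[["MC"]])
    fC1 <- driftFrequencies(pC, divergence[["C12"]])
    fC2 <- if (divergence[["C12"]] == 0) fC1 else
      driftFrequencies(pC, divergence[["C12"]])
    nFixed <- round(nSites * outgroupFixedFraction)
    fixed <- logical(nSites)
    fixed[sample.int(nSites, nFixed)] <- TRUE
    fO <- numeric(nSites)
    if (any(!fixed)) {
      og <- driftFrequencies(pAnc[!fixed], divergence[["outgroup"]])
      fO[!fixed] <- pmin(pmax(og, 0.01), 0.99)  # keep non-fixed sites truly polymorphic
    }
    chrom <- sort(rep_len(paste0("chr", seq_len(nChromosomes)), nSites))
    pos <- unlist(lapply(split(seq_len(nSites), chrom),
                         function(i) sort(sample.int(10L * nSites,
                                                     length(i)))),
                  use.names = FALSE)
    alleles <- t(vapply(seq_len(nSites),
                        function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2L)))
    freq <- cbind(M = fM, C1 = fC1, C2 = fC2, outgroup = fO)
    sites <- .siteRanges(chrom, pos, alleles[, 1L], alleles[, 2L])
    S4Vectors::mcols(sites)$outgroupFixed <- fixed
    .newSiteExperiment("LineagePanel", list(freq = freq), sites,
                       c("M", "C1", "C2", "outgroup"),
                       metadata = list(divergence = divergence,
                                       outgroupFixedFraction =
                                         outgroupFixedFraction,
                                       seed = seed))
  })
}

#' Simulate one polyandrous colony
#'
#' Realizes the workers of a colony under haplodiploid inheritance: the
#' diploid queen carries two haplotypes whose alleles are drawn per site from
#' a mixture of the M and donor-C lineage frequencies weighted by her
#' ancestry; each haploid drone mate carries one haplotype drawn likewise
#' from his own ancestry.  Every worker receives one queen gamete
#' (haplotypes segregating independently per site, i.e. free recombination)
#' and the full haplotype of a drone chosen by the patriline weights.
#'
#' @param spec a \linkS4class{ColonySpec}.
#' @param panel a \linkS4class{LineagePanel} supplying lineage frequencies.
#' @param seed integer seed.
#' @return a \linkS4class{WorkerSet} with one column per worker;
#'   \code{colData()$patriline} gives each worker's drone of origin and
#'   \code{metadata()$spec} the generating specification.
#' @examples
#' panel <- simulateLineagePanel(50, seed = 1)
#' ws <- simulateColony(ColonySpec(0.5, c(0, 1)), panel, seed = 2)
#' table(SummarizedExperiment::colData(ws)$patriline)
#' @export
simulateColony <- function(spec, panel, seed = NULL) {
  stopifnot(is(spec, "ColonySpec"), is(panel, "LineagePanel"))
  validObject(spec)
  S <- nrow(panel)
  fM <- alleleFreq(panel)[, "M"]
  fC <- alleleFreq(panel)[, spec@donorLineage]
  nD <- length(spec@droneAncestries)
  W <- spec@nWorkersPool
  .withSeed(seed, {
    mixFreq <- function(ancestry)
      ifelse(rbinom(S, 1L, ancestry) == 1L, fC, fM)
    queenHap <- cbind(rbinom(S, 1L, mixFreq(spec@queenAncestry)),
                      rbinom(S, 1L, mixFreq(spec@queenAncestry)))
    droneHap <- vapply(spec@droneAncestries,
                       function(a) rbinom(S, 1L, mixFreq(a)), integer(S))
    droneHap <- matrix(droneHap, nrow = S)
    father <- sample.int(nD, W, replace = TRUE, prob = spec@patrilineWeights)
    pick <- matrix(rbinom(S * W, 1L, 0.5) + 1L, nrow = S)
    maternal <- matrix(queenHap[cbind(rep(seq_len(S), W), as.vector(pick))],
                       nrow = S)
    paternal <- droneHap[, father, drop = FALSE]
    dosage <- maternal + paternal
    ids <- sprintf("worker%02d", seq_len(W))
    .newSiteExperiment("WorkerSet",
      list(dosage = dosage, maternal = maternal, paternal = paternal),
      rowRanges(panel), ids,
      colData = S4Vectors::DataFrame(patriline = father, row.names = ids),
      metadata = list(spec = spec, seed = seed))
  })
}

#' True pooled allele frequency of a worker set
#'
#' The per-site derived-allele frequency of the pool formed by all workers
#' contributing equimolar DNA: mean dosage over workers divided by 2.
#'
#' @param workers a \linkS4class{WorkerSet}.
#' @return numeric vector of per-site frequencies.
#' @export
poolTrueFrequency <- function(workers) {
  rowMeans(dosage(workers)) / 2
}

#' Sequence a colony pool
#'
#' Simulates pooled sequencing of a worker set under equimolar contribution:
#' total depth per site is Poisson with the stated mean, and the alternate
#' read count is binomial with success probability equal to the pool's true
#' derived-allele frequency.
#'
#' @param workers a \linkS4class{WorkerSet} with at least one worker.
#' @param meanDepth positive mean read depth (the study design uses 40x).
#' @param sampleId name of the pooled sample.
#' @param seed integer seed.
#' @return a one-sample \linkS4class{PoolCounts}.
#' @examples
#' panel <- simulateLineagePanel(50, seed = 1)
#' ws <- simulateColony(ColonySpec(0, 0), panel, seed = 2)
#' pc <- sequencePool(ws, meanDepth = 40, seed = 3)
#' summary(as.vector(poolDepth(pc)))
#' @export
sequencePool <- function(workers, meanDepth = 40, sampleId = "pool1",
                        seed = NULL) {
  stopifnot(is(workers, "WorkerSet"))
  if (ncol(workers) < 1L) stop("at least one worker is required")
  if (meanDepth <= 0) stop("meanDepth must be positive")
  p <- poolTrueFrequency(workers)
  S <- nrow(workers)
  .withSeed(seed, {
    dp <- rpois(S, meanDepth)
    alt <- rbinom(S, dp, p)
  })
  .newSiteExperiment("PoolCounts",
    list(adRef = dp - alt, adAlt = alt, dp = dp),
    rowRanges(workers), sampleId,
    metadata = list(meanDepth = meanDepth, seed = seed))
}

#' Sample a single worker from a colony
#'
#' Chooses one worker uniformly at random and returns its exact diploid
#' genotypes, mirroring study designs in which one individual stands in for
#' the whole colony.
#'
#' @param workers a \linkS4class{WorkerSet} with at least one worker.
#' @param sampleId name for the sampled individual.
#' @param seed integer seed.
#' @return a one-sample \linkS4class{GenotypeMatrix};
#'   \code{metadata()$workerIndex} records which worker was drawn.
#' @export
sampleIndividual <- function(workers, sampleId = "individual1", seed = NULL) {
  stopifnot(is(workers, "WorkerSet"))
  if (ncol(workers) < 1L) stop("at least one worker is required")
  idx <- .withSeed(seed, sample.int(ncol(workers), 1L))
  g <- dosage(workers)[, idx, drop = FALSE]
  .newSiteExperiment("GenotypeMatrix", list(dosage = g),
                     rowRanges(workers), sampleId,
                     metadata = list(workerIndex = idx, seed = seed))
}

#' Expected colony C-lineage fraction under a colony specification
#'
#' Closed-form expectation of the pool's C-lineage ancestry: half the queen's
#' ancestry plus half the patriline-weighted mean drone ancestry, since each
#' worker draws one gamete from each side.
#'
#' @param spec a \linkS4class{ColonySpec}.
#' @return a single numeric expectation in [0, 1].
#' @examples
#' expectedColonyAncestry(ColonySpec(0.5, 1.0))  # 0.75
#' @export
expectedColonyAncestry <- function(spec) {
  stopifnot(is(spec, "ColonySpec"))
  spec@queenAncestry / 2 +
    sum(spec@patrilineWeights * spec@droneAncestries) / 2
}
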