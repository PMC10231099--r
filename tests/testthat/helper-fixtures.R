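# Small builders and independent oracles shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# FrequencyMatrix from a plain matrix, generic coordinates.
tinyFreq <- function(m, sampleIds = colnames(m)) {
  m <- as.matrix(m)
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(m)))
  FrequencyMatrix(m, chrom = rep("chr1", nrow(m)), pos = seq_len(nrow(m)),
                  ref = rep("A", nrow(m)), alt = rep("T", nrow(m)),
                  sampleIds = sampleIds)
}

# GenotypeMatrix from a plain dosage matrix.
tinyGeno <- function(m, sampleIds = colnames(m)) {
  m <- as.matrix(m)
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(ncol(m)))
  GenotypeMatrix(m, chrom = rep("chr1", nrow(m)), pos = seq_len(nrow(m)),
                 ref = rep("A", nrow(m)), alt = rep("T", nrow(m)),
                 sampleIds = sampleIds)
}

# Hudson's FST estimator (ratio of averages) on population frequencies —
# independent oracle for the drift generator.
hudsonFst <- function(p1, p2) {
  sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
}

# Brute-force site-pattern oracle: enumerate all 8 haploid allele
# configurations of (P1, P2, P3) with the outgroup ancestral, weight each by
# its probability under the site frequencies, and sum the ABBA/BABA
# indicator patterns.
enumeratePatternSums <- function(p1, p2, p3) {
  abba <- 0; baba <- 0
  for (x1 in 0:1) for (x2 in 0:1) for (x3 in 0:1) {
    pr <- (p1^x1 * (1 - p1)^(1 - x1)) *
          (p2^x2 * (1 - p2)^(1 - x2)) *
          (p3^x3 * (1 - p3)^(1 - x3))
    if (x1 == 0 && x2 == 1 && x3 == 1) abba <- abba + sum(pr)
    if (x1 == 1 && x2 == 0 && x3 == 1) baba <- baba + sum(pr)
  }
  c(abba = abba, baba = baba)
}

# Pooled-colony frequency column for battery-style tests: simulate a colony
# against a panel, sequence it, estimate frequencies.
poolFreqColumn <- function(spec, panel, seed, depth = 40) {
  ws <- simulateColony(spec, panel, seed = seed)
  pc <- sequencePool(ws, depth, seed = seed + 50000L)
  as.vector(alleleFreq(estimatePoolFrequencies(pc)))
}

# Reference panel of pure pooled colonies (nEach per subspecies) plus its
# polarized frequency matrix, for trio battery tests.
buildReferenceSet <- function(panel, nEach = 6, nDrones = 8, seed0 = 0) {
  cols <- list()
  for (i in seq_len(nEach))
    cols[[paste0("mel", i)]] <-
      poolFreqColumn(ColonySpec(0, rep(0, nDrones)), panel, seed0 + i)
  for (i in seq_len(nEach))
    cols[[paste0("car", i)]] <-
      poolFreqColumn(ColonySpec(1, rep(1, nDrones), donorLineage = "C1"),
                     panel, seed0 + 100 + i)
  for (i in seq_len(nEach))
    cols[[paste0("lig", i)]] <-
      poolFreqColumn(ColonySpec(1, rep(1, nDrones), donorLineage = "C2"),
                     panel, seed0 + 200 + i)
  qt <- data.frame(colony = names(cols),
                   subspecies = rep(c("mellifera", "carnica", "ligustica"),
                                    each = nEach),
                   q = 1)
  list(freqs = do.call(cbind, cols), panel = selectReferenceColonies(qt))
}
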