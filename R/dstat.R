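#' Polarize in-group frequencies against a fixed outgroup
#'
#' ABBA BABA statistics require the ancestral allele state, defined here by
#' an outgroup fixed at the site.  Sites where the outgroup frequency is not
#' exactly 0 or 1 are discarded; where the outgroup is fixed for the
#' alternate allele (frequency 1) all in-group frequencies are flipped
#' (\code{p -> 1 - p}) so that the outgroup allele is ancestral ("A") and the
#' reported frequencies count the derived allele ("B").
#'
#' @param freqs a \linkS4class{FrequencyMatrix} of in-group samples.
#' @param outgroup either a numeric vector of outgroup allele frequencies
#'   aligned with \code{freqs}, or a one-sample \linkS4class{FrequencyMatrix}
#'   on the same sites.
#' @return a \linkS4class{FrequencyMatrix} restricted to outgroup-fixed
#'   sites, polarized so the derived allele is counted.
#' @examples
#' fm <- FrequencyMatrix(matrix(c(0.2, 0.9), 2), chrom = c("1", "1"),
#'                       pos = 1:2, ref = c("A", "A"), alt = c("T", "T"),
#'                       sampleIds = "s1")
#' alleleFreq(polarizeFrequencies(fm, c(1, 0.3)))  # site 1 flipped to 0.8
#' @export
polarizeFrequencies <- function(freqs, outgroup) {
  stopifnot(is(freqs, "FrequencyMatrix"))
  if (is(outgroup, "FrequencyMatrix")) {
    shared <- intersectSites(freqs, outgroup)
    freqs <- shared$a
    outgroup <- as.vector(alleleFreq(shared$b)[, 1L])
  }
  if (length(outgroup) != nrow(freqs))
    stop("outgroup frequencies must align with the in-group sites")
  fixed <- !is.na(outgroup) & (outgroup == 0 | outgroup == 1)
  if (!any(fixed))
    stop("no sites with a fixed outgroup: cannot polarize")
  out <- freqs[fixed, ]
  og <- outgroup[fixed]
  f <- alleleFreq(out)
  f[og == 1, ] <- 1 - f[og == 1, , drop = FALSE]
  assay(out, "freq") <- f
  .logStage(out, "polarize", nrow(freqs), nrow(out), ncol(out))
}

# Internal: contiguous blocks of near-equal SNP count; the remainder
# r = n %% nBlocks is spread one extra SNP per block starting from block 1,
# so block sizes differ by at most one.
.assignBlocks <- function(n, nBlocks) {
  if (nBlocks < 2L) stop("at least 2 jackknife blocks are required")
  if (n < nBlocks) stop("fewer sites than jackknife blocks")
  base <- n %/% nBlocks
  sizes <- rep(base, nBlocks) + rep(c(1L, 0L), c(n %% nBlocks,
                                                 nBlocks - n %% nBlocks))
  rep(seq_len(nBlocks), times = sizes)
}

#' Assemble a polarized four-taxon test
#'
#' Collects the per-site derived-allele frequencies of the three in-group
#' populations (and optionally a second donor-lineage representative used by
#' the f estimator) from a polarized frequency matrix, drops sites with any
#' missing frequency listwise, and assigns the surviving sites to contiguous
#' jackknife blocks of equal SNP count (sizes differ by at most one; 10,500
#' sites in 20 blocks give exactly 525 SNPs per block).
#'
#' @param freqs a polarized \linkS4class{FrequencyMatrix} (see
#'   [polarizeFrequencies()]), or a plain numeric matrix of polarized
#'   frequencies with samples as columns.
#' @param p1,p2,p3 column names (or indices) of the populations at the P1,
#'   P2 and P3 positions of the tree.
#' @param p3a optional column for a second P3-lineage representative.
#' @param nBlocks number of jackknife blocks (default 20).
#' @return a \linkS4class{PolarizedTrio}.
#' @export
makeTrio <- function(freqs, p1, p2, p3, p3a = NULL, nBlocks = 20L) {
  f <- if (is(freqs, "FrequencyMatrix")) alleleFreq(freqs) else as.matrix(freqs)
  ids <- rownames(f)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(f)))
  cols <- c(p1, p2, p3, p3a)
  m <- f[, cols, drop = FALSE]
  ok <- complete.cases(m)
  m <- m[ok, , drop = FALSE]
  new("PolarizedTrio",
      p1 = m[, 1L], p2 = m[, 2L], p3 = m[, 3L],
      p3a = if (is.null(p3a)) numeric(0) else m[, 4L],
      blockId = .assignBlocks(nrow(m), nBlocks),
      siteId = ids[ok], nDropped = as.integer(sum(!ok)))
}

#' ABBA and BABA site-pattern sums from allele frequencies
#'
#' With the outgroup ancestral by construction, the frequency-weighted
#' expected count of ABBA patterns at site i is
#' \eqn{(1 - p_{1i}) p_{2i} p_{3i}} and of BABA patterns
#' \eqn{p_{1i} (1 - p_{2i}) p_{3i}}; the sums over sites are the numerator
#' components of Patterson's D.  Degenerate sites (all frequencies equal)
#' contribute equally to both sums and so cancel in D.
#'
#' @param trio a \linkS4class{PolarizedTrio}.
#' @return named numeric vector with elements \code{abba} and \code{baba}.
#' @examples
#' trio <- makeTrio(cbind(a = c(0, 0), b = c(1, 1), c = c(1, 1)),
#'                  "a", "b", "c", nBlocks = 2)
#' sitePatternSums(trio)  # two pure ABBA sites
#' @export
sitePatternSums <- function(trio) {
  stopifnot(is(trio, "PolarizedTrio"))
  c(abba = sum((1 - trio@p1) * trio@p2 * trio@p3),
    baba = sum(trio@p1 * (1 - trio@p2) * trio@p3))
}

#' Patterson's D statistic
#'
#' \eqn{D = (ABBA - BABA) / (ABBA + BABA)} over the frequency-weighted
#' pattern sums.  D near 0 is consistent with incomplete lineage sorting
#' alone; D > 0 indicates an excess of derived alleles shared by P2 and P3
#' (gene flow between them), D < 0 an excess shared by P1 and P3.  Swapping
#' P1 and P2 negates D exactly.
#'
#' @param trio a \linkS4class{PolarizedTrio}.
#' @return D in [-1, 1].
#' @export
pattersonD <- function(trio) {
  s <- sitePatternSums(trio)
  if (sum(s) <= 0)
    stop("ABBA + BABA sums to zero: D is undefined")
  unname((s["abba"] - s["baba"]) / (s["abba"] + s["baba"]))
}

# Per-site numerator/denominator contributions of D and f, shared by the
# full statistic and its jackknife.
.trioTerms <- function(trio, statistic) {
  if (statistic == "D") {
    list(num = trio@p3 * (trio@p2 - trio@p1),
         den = (1 - trio@p1) * trio@p2 * trio@p3 +
               trio@p1 * (1 - trio@p2) * trio@p3)
  } else {
    if (!length(trio@p3a))
      stop("statistic 'f' requires a second donor representative (p3a)")
    list(num = trio@p3 * (trio@p2 - trio@p1),
         den = trio@p3 * (trio@p3a - trio@p1))
  }
}

#' Equal-SNP-count block jackknife for D or f
#'
#' Delete-one-block jackknife over the contiguous blocks carried by the trio:
#' for each block the statistic is recomputed from the remaining sites, and
#' \deqn{SE = \sqrt{\frac{n-1}{n} \sum_i (\theta_{-i} - \bar\theta_{-\cdot})^2}}
#' with n the number of blocks; \eqn{Z = \theta / SE}.  Blocks of equal SNP
#' count keep the leave-one-out estimates equally weighted even where
#' genotyping density varies along the genome.
#'
#' @param trio a \linkS4class{PolarizedTrio}.
#' @param statistic \code{"D"} or \code{"f"}.
#' @return a list with \code{theta} (the full-data statistic), \code{se},
#'   \code{z} and \code{nBlocks}.
#' @export
blockJackknife <- function(trio, statistic = c("D", "f")) {
  stopifnot(is(trio, "PolarizedTrio"))
  statistic <- match.arg(statistic)
  terms <- .trioTerms(trio, statistic)
  numB <- tapply(terms$num, trio@blockId, sum)
  denB <- tapply(terms$den, trio@blockId, sum)
  numT <- sum(numB); denT <- sum(denB)
  if (statistic == "D" && denT <= 0)
    stop("ABBA + BABA sums to zero: D is undefined")
  if (statistic == "f" && denT <= 0)
    stop("complete-admixture denominator is not positive: f is undefined")
  theta <- numT / denT
  loo <- (numT - numB) / (denT - denB)
  n <- length(numB)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(theta = unname(theta), se = unname(se),
       z = unname(theta / se), nBlocks = n)
}

#' Two-sided p-value from a jackknife Z score
#'
#' \eqn{p = 2 (1 - \Phi(|Z|))} under the standard normal reference
#' distribution of the block-jackknife Z.
#'
#' @param z finite Z score(s).
#' @return two-sided p-value(s) in [0, 1].
#' @examples
#' zToPValue(0)      # 1
#' zToPValue(1.96)   # ~0.05
#' @export
zToPValue <- function(z) {
  if (any(!is.finite(z))) stop("Z must be finite")
  2 * pnorm(-abs(z))
}

#' f admixture-proportion estimator
#'
#' Compares the observed ABBA-BABA excess to the excess expected under
#' complete admixture, obtained by substituting the test population P2 with a
#' second donor-lineage representative:
#' \deqn{f = \frac{S(p_1, p_2, p_{3b})}{S(p_1, p_{3a}, p_{3b})}, \quad
#'       S(a, b, c) = \sum_i c_i (b_i - a_i)}
#' where \eqn{p_{3a}} occupies the P2 slot of the denominator and
#' \eqn{p_{3b}} the P3 slot of both.  When only one donor representative is
#' available the same vector may serve in both slots, which biases f upward;
#' [dstatTest()] flags that case.
#'
#' @param trio a \linkS4class{PolarizedTrio} carrying \code{p3a}; its
#'   \code{p3a} fills the denominator's P2 slot and \code{p3} the P3 slot.
#' @return the f estimate (a proportion; may fall marginally outside [0, 1]
#'   from sampling noise and is reported as-is).
#' @export
admixtureF <- function(trio) {
  terms <- .trioTerms(trio, "f")
  den <- sum(terms$den)
  if (den <= 0)
    stop("complete-admixture denominator is not positive: f is undefined")
  sum(terms$num) / den
}

#' f4-ratio estimate of the admixture proportion
#'
#' Estimates the donor-lineage ancestry fraction alpha of a test population X
#' from two f4 statistics.  Populations A and B are two representatives of
#' the donor lineage (a sister pair), C is a recipient-lineage reference and
#' the outgroup O is ancestral (frequency 0) after polarization:
#' \deqn{\alpha = \frac{f4(A, O; X, C)}{f4(A, O; B, C)}, \quad
#'       f4(W, X; Y, Z) = \frac{1}{n}\sum_i (p_{Wi} - p_{Xi})(p_{Yi} - p_{Zi})}
#' Alpha is the proportion of X's ancestry contributed by the donor lineage,
#' reported with its complement \code{1 - alpha}; X identical to B gives
#' alpha = 1, X drawn from the recipient lineage gives alpha near 0.
#'
#' @param donorA,donorB per-site polarized frequencies of the two
#'   donor-lineage representatives.
#' @param test per-site polarized frequencies of the admixed population X.
#' @param recipient per-site polarized frequencies of the recipient-lineage
#'   reference C.
#' @param outgroup per-site outgroup frequencies (0 after polarization).
#' @return a named numeric vector with \code{alpha} and \code{oneMinusAlpha}.
#' @examples
#' p <- runif(100)
#' f4Ratio(p, p, p, runif(100))["alpha"]  # X == B: exactly 1
#' @export
f4Ratio <- function(donorA, donorB, test, recipient,
                    outgroup = rep(0, length(donorA))) {
  n <- length(donorA)
  stopifnot(length(donorB) == n, length(test) == n,
            length(recipient) == n, length(outgroup) == n)
  f4 <- function(w, x, y, z) mean((w - x) * (y - z))
  den <- f4(donorA, outgroup, donorB, recipient)
  if (abs(den) < 1e-12)
    stop("f4 denominator is numerically zero: the ratio is undefined")
  alpha <- f4(donorA, outgroup, test, recipient) / den
  c(alpha = alpha, oneMinusAlpha = 1 - alpha)
}

#' Run one complete ABBA BABA test
#'
#' Computes pattern sums, Patterson's D, the block-jackknife standard error,
#' Z and two-sided p-value, and — when a second donor representative is
#' present — the f admixture proportion, for one polarized trio.
#'
#' @param trio a \linkS4class{PolarizedTrio}.
#' @param labels optional named character vector of population labels
#'   (\code{P1}, \code{P2}, \code{P3}).
#' @return a \linkS4class{TrioResult}.
#' @examples
#' panel <- simulateLineagePanel(2000, seed = 1, outgroupFixedFraction = 1)
#' f <- alleleFreq(panel)
#' trio <- makeTrio(f[, 1:3], "M", "C1", "C2", nBlocks = 20)
#' dstatTest(trio)
#' @export
dstatTest <- function(trio, labels = c(P1 = "P1", P2 = "P2", P3 = "P3")) {
  s <- sitePatternSums(trio)
  jk <- blockJackknife(trio, "D")
  fval <- NA_real_
  if (length(trio@p3a)) {
    if (identical(trio@p3a, trio@p3))
      warning("single donor representative used in both f slots: ",
              "f is biased upward")
    fval <- admixtureF(trio)
  }
  new("TrioResult", populations = labels,
      abbaSum = unname(s["abba"]), babaSum = unname(s["baba"]),
      D = jk$theta, jackknifeSE = jk$se, Z = jk$z,
      pValue = if (is.finite(jk$z)) zToPValue(jk$z)
               else if (is.nan(jk$z)) NA_real_ else 0,
      f = fval,
      nSites = length(trio@p1), nBlocks = as.integer(jk$nBlocks))
}
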