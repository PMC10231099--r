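# Log-likelihood of the binomial admixture model; missing entries skipped.
.admixLogLik <- function(G, Q, F, eps = 1e-9) {
  H <- Q %*% F
  H <- pmin(pmax(H, eps), 1 - eps)
  sum(G * log(H) + (2 - G) * log(1 - H), na.rm = TRUE)
}

#' Fit a maximum-likelihood admixture model
#'
#' Estimates ancestry membership proportions Q (samples x K, rows on the
#' simplex) and cluster allele frequencies F (K x sites) maximizing the
#' binomial admixture log-likelihood
#' \deqn{\sum_{ij} g_{ij} \ln\left(\sum_k q_{ik} f_{kj}\right) +
#'       (2 - g_{ij}) \ln\left(\sum_k q_{ik} (1 - f_{kj})\right)}
#' by multiplicative EM updates, which are monotone in the log-likelihood.
#' Supervised mode fixes the Q rows of labelled reference samples to unit
#' vectors on their cluster, the usual way subspecies standards calibrate an
#' introgression analysis.  Missing genotypes are skipped in all sums.  F is
#' clamped to \code{[eps, 1 - eps]} to keep the likelihood finite.
#'
#' Iteration stops when the log-likelihood improves by less than \code{tol}
#' or after \code{maxIter} iterations.  With \code{nStarts > 1} the model is
#' refit from that many jittered initializations and the best likelihood is
#' kept (the fit is deterministic given \code{seed}).
#'
#' @param G a \linkS4class{GenotypeMatrix}, or a samples-by-sites numeric
#'   matrix of dosages in \{0, 1, 2\} with \code{NA} for missing.
#' @param K number of ancestral clusters; K = 1 is the degenerate
#'   single-cluster baseline used by cross-validation.
#' @param supervised optional named character vector mapping reference sample
#'   ids to cluster labels; every cluster label used must appear at least
#'   once, and clusters are ordered by first appearance of their label.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations (default 2000).
#' @param nStarts random restarts (default 1).
#' @param eps clamp for cluster frequencies (default 1e-6).
#' @param initQ,initF optional initial matrices (overrides random init).
#' @param seed integer seed for the initialization jitter.
#' @return an \linkS4class{AdmixtureFit}.
#' @examples
#' panel <- simulateLineagePanel(300, seed = 1)
#' f <- alleleFreq(panel)
#' G <- rbind(m = rbinom(300, 2, f[, "M"]), c = rbinom(300, 2, f[, "C1"]))
#' fit <- fitAdmixture(G, K = 2, supervised = c(m = "M", c = "C"), seed = 1)
#' @export
fitAdmixture <- function(G, K = 2L, supervised = NULL, tol = 1e-6,
                         maxIter = 2000L, nStarts = 1L, eps = 1e-6,
                         initQ = NULL, initF = NULL, seed = NULL) {
  if (is(G, "GenotypeMatrix")) G <- t(dosage(G))
  G <- as.matrix(G)
  I <- nrow(G); J <- ncol(G)
  if (K < 1L) stop("K must be at least 1")
  if (K > I) stop("K cannot exceed the number of samples")
  if (is.null(rownames(G))) rownames(G) <- paste0("sample", seq_len(I))
  supRows <- integer(0); supQ <- NULL
  clusterNames <- paste0("cluster", seq_len(K))
  if (!is.null(supervised)) {
    labs <- unique(unname(supervised))
    if (length(labs) > K)
      stop("more supervised labels than clusters")
    clusterNames[seq_along(labs)] <- labs
    supRows <- match(names(supervised), rownames(G))
    if (anyNA(supRows))
      stop("supervised ids absent from the genotype matrix: ",
           paste(names(supervised)[is.na(supRows)], collapse = ", "))
    supQ <- matrix(0, length(supRows), K)
    supQ[cbind(seq_along(supRows), match(supervised, labs))] <- 1
  }
  miss <- is.na(G)
  Gz <- G; Gz[miss] <- 0
  G2z <- 2 - G; G2z[miss] <- 0
  nObs <- rowSums(!miss)
  if (any(nObs == 0)) stop("sample(s) with no observed genotypes")

  emRun <- function(Q, F) {
    ll <- numeric(0)
    llPrev <- -Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      H <- Q %*% F
      H <- pmin(pmax(H, 1e-12), 1 - 1e-12)
      A <- Gz / H
      B <- G2z / (1 - H)
      QtA <- crossprod(Q, A)          # K x J
      QtB <- crossprod(Q, B)
      Fnew <- (F * QtA) / (F * QtA + (1 - F) * QtB)
      Fnew[!is.finite(Fnew)] <- F[!is.finite(Fnew)]
      Fnew <- pmin(pmax(Fnew, eps), 1 - eps)
      Qnew <- Q * (A %*% t(F) + B %*% t(1 - F)) / (2 * nObs)
      Qnew <- Qnew / rowSums(Qnew)
      if (length(supRows)) Qnew[supRows, ] <- supQ
      Q <- Qnew; F <- Fnew
      llNow <- .admixLogLik(G, Q, F)
      if (!is.finite(llNow))
        stop("non-finite log-likelihood at iteration ", it)
      ll <- c(ll, llNow)
      if (llNow - llPrev < tol && it > 1L) { converged <- TRUE; break }
      llPrev <- llNow
    }
    list(Q = Q, F = F, ll = ll, converged = converged)
  }

  initOne <- function() {
    Q <- if (!is.null(initQ)) initQ else {
      q <- matrix(rgamma(I * K, shape = 1), I, K)  # Dirichlet(1) rows
      q / rowSums(q)
    }
    if (length(supRows)) Q[supRows, ] <- supQ
    F <- if (!is.null(initF)) initF else
      matrix(runif(K * J, 0.05, 0.95), K, J)
    list(Q = Q, F = F)
  }

  best <- .withSeed(seed, {
    fits <- lapply(seq_len(max(1L, nStarts)), function(s) {
      ini <- initOne()
      emRun(ini$Q, ini$F)
    })
    fits[[which.max(vapply(fits, function(f) f$ll[length(f$ll)], 0))]]
  })
  dimnames(best$Q) <- list(rownames(G), clusterNames)
  dimnames(best$F) <- list(clusterNames, colnames(G))
  new("AdmixtureFit", Q = best$Q, F = best$F, logLik = best$ll,
      K = as.integer(K), converged = best$converged,
      supervised = if (length(supRows)) rownames(G)[supRows] else character(0))
}

#' Cross-validation over the number of ancestry clusters
#'
#' For each candidate K, a fraction of the non-missing genotype entries is
#' masked per fold, the admixture model is refit on the remaining entries,
#' and the masked dosages are predicted as \eqn{2 \sum_k q_{ik} f_{kj}}.
#' The CV error is the mean squared deviation over masked entries, averaged
#' over folds; the most likely K attains the minimum.  A masking that would
#' leave a sample or site fully unobserved is redrawn with a warning.
#'
#' @param G dosage input as in [fitAdmixture()].
#' @param Krange candidate cluster numbers (e.g. \code{1:3}).
#' @param nFolds number of folds (default 5).
#' @param maskFraction fraction of observed entries masked per fold
#'   (default \code{1/nFolds}); must be positive.
#' @param seed integer seed governing masking and initialization.
#' @param ... further arguments passed to [fitAdmixture()].
#' @return an \linkS4class{AdmixtureCV}.
#' @export
crossValidation <- function(G, Krange = 1:3, nFolds = 5L,
                            maskFraction = 1 / nFolds, seed = NULL, ...) {
  if (is(G, "GenotypeMatrix")) G <- t(dosage(G))
  G <- as.matrix(G)
  if (!length(Krange)) stop("Krange must be nonempty")
  if (maskFraction <= 0)
    stop("maskFraction must be positive: masking nothing is a degenerate CV")
  obs <- which(!is.na(G))
  err <- .withSeed(seed, {
    folds <- lapply(seq_len(nFolds), function(fold) {
      for (try in 1:20) {
        mask <- sample(obs, max(1L, round(length(obs) * maskFraction)))
        Gm <- G
        Gm[mask] <- NA
        if (all(rowSums(!is.na(Gm)) > 0) && all(colSums(!is.na(Gm)) > 0))
          return(list(mask = mask, Gm = Gm))
        warning("masking left a sample or site unobserved; refolding")
      }
      stop("could not draw a valid mask in 20 attempts")
    })
    vapply(Krange, function(K) {
      mean(vapply(folds, function(fd) {
        fit <- fitAdmixture(fd$Gm, K = K, seed = sample.int(2^30, 1L), ...)
        pred <- 2 * (qMatrix(fit) %*% fMatrix(fit))
        mean((G[fd$mask] - pred[fd$mask])^2)
      }, 0))
    }, 0)
  })
  names(err) <- as.character(Krange)
  new("AdmixtureCV", error = err,
      chosenK = as.integer(Krange[which.min(err)]),
      nFolds = as.integer(nFolds), maskFraction = maskFraction)
}

#' Convert pooled frequencies to pseudo-genotypes
#'
#' Admixture models consume genotypes; pooled samples provide frequencies.
#' Two encodings are offered: \code{"round-dosage"} sets the dosage to
#' \code{round(2 f)}; \code{"threshold"} calls 0 below 1/3, 1 up to 2/3 and
#' 2 above.  The rule is recorded in the result's metadata because the
#' choice is a modelling decision, not a detail.
#'
#' @param freqs a \linkS4class{FrequencyMatrix}.
#' @param rule \code{"round-dosage"} (default) or \code{"threshold"}.
#' @return a \linkS4class{GenotypeMatrix} on the same sites and samples.
#' @examples
#' fm <- FrequencyMatrix(matrix(c(0, 0.5, 0.75)), chrom = rep("1", 3),
#'                       pos = 1:3, ref = rep("A", 3), alt = rep("T", 3),
#'                       sampleIds = "pool1")
#' dosage(poolToPseudogenotypes(fm))
#' @export
poolToPseudogenotypes <- function(freqs, rule = c("round-dosage",
                                                  "threshold")) {
  stopifnot(is(freqs, "FrequencyMatrix"))
  rule <- match.arg(rule)
  f <- alleleFreq(freqs)
  g <- switch(rule,
    "round-dosage" = round(2 * f),
    "threshold" = ifelse(f < 1 / 3, 0L, ifelse(f <= 2 / 3, 1L, 2L)))
  storage.mode(g) <- "integer"
  md <- S4Vectors::metadata(freqs)
  md$pseudogenotypeRule <- rule
  .newSiteExperiment("GenotypeMatrix", list(dosage = g), rowRanges(freqs),
                     colnames(freqs), metadata = md)
}

#' C-lineage membership from a K = 2 admixture fit
#'
#' Resolves which of the two clusters represents the C lineage — by the
#' supervised labels when present, otherwise by which cluster the given
#' C-lineage reference samples load on — and returns every sample's
#' membership to it.  References splitting across clusters (mean membership
#' difference below 0.5) make the identity ambiguous and raise an error.
#'
#' @param fit a K = 2 \linkS4class{AdmixtureFit}.
#' @param cReferences character ids of known C-lineage reference samples, or
#'   a cluster label used in the supervised fit (e.g. \code{"C"}).
#' @return named numeric vector of per-sample C-lineage Q values.
#' @export
cLineageQ <- function(fit, cReferences) {
  stopifnot(is(fit, "AdmixtureFit"))
  if (fit@K != 2L) stop("C-lineage membership is defined for K = 2")
  Q <- qMatrix(fit)
  if (length(cReferences) == 1L && cReferences %in% colnames(Q))
    return(Q[, cReferences])
  idx <- match(cReferences, rownames(Q))
  if (anyNA(idx))
    stop("reference sample(s) absent from the fit: ",
         paste(cReferences[is.na(idx)], collapse = ", "))
  load <- colMeans(Q[idx, , drop = FALSE])
  if (abs(load[1L] - load[2L]) < 0.5)
    stop("C-lineage references split across clusters: identity ambiguous")
  Q[, which.max(load)]
}
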