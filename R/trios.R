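#' Select reference colonies by ancestry membership
#'
#' Builds the reference panels for the trio battery: only colonies whose
#' ancestry membership (Q) to the cluster of their putative subspecies
#' reaches the threshold are admitted, so that the P1 and P3 standards carry
#' low or no introgression.  The default threshold of 0.99 is deliberately
#' strict.
#'
#' @param qTable a data.frame with columns \code{colony}, \code{subspecies}
#'   (e.g. \code{mellifera}, \code{carnica}, \code{ligustica}) and \code{q},
#'   the colony's membership to its own subspecies cluster.
#' @param threshold minimum own-cluster Q (default 0.99).
#' @return a \linkS4class{ReferencePanel}; an error names any subspecies
#'   group left empty by the selection.
#' @examples
#' qt <- data.frame(colony = c("m1", "m2", "c1"),
#'                  subspecies = c("mellifera", "mellifera", "carnica"),
#'                  q = c(0.995, 0.98, 1.0))
#' selectReferenceColonies(qt)
#' @export
selectReferenceColonies <- function(qTable, threshold = 0.99) {
  need <- c("colony", "subspecies", "q")
  if (!all(need %in% colnames(qTable)))
    stop("qTable must have columns 'colony', 'subspecies', 'q'")
  if (any(qTable$q < 0 | qTable$q > 1))
    stop("Q values must lie in [0, 1]")
  if (any(duplicated(qTable$colony)))
    stop("duplicate colony ids in qTable")
  pass <- qTable[qTable$q >= threshold, ]
  groups <- split(pass$colony, pass$subspecies)
  empty <- setdiff(unique(qTable$subspecies), names(groups))
  if (length(empty))
    stop("no colony passed the Q threshold for group(s): ",
         paste(empty, collapse = ", "))
  groups <- lapply(groups, sort)
  new("ReferencePanel", groups = groups, qTable = qTable,
      threshold = threshold)
}

#' Enumerate the trio test battery for a focal colony
#'
#' Forms every (P1, focal, P3) combination with P1 drawn from the
#' \emph{A. m. mellifera} reference panel and P3 from each donor panel
#' (\emph{A. m. carnica}, \emph{A. m. ligustica}), tagging each test by
#' donor subspecies.  Six colonies in each panel yield 36 + 36 = 72 tests
#' per focal colony.
#'
#' @param focal focal colony id (takes the P2 position).
#' @param panel a \linkS4class{ReferencePanel} with a \code{mellifera} group
#'   and at least one donor group.
#' @param recipientGroup name of the P1 (recipient-lineage) group.
#' @return a data.frame with columns \code{p1}, \code{p2}, \code{p3},
#'   \code{donor}.
#' @export
enumerateTrios <- function(focal, panel, recipientGroup = "mellifera") {
  stopifnot(is(panel, "ReferencePanel"))
  mel <- panel@groups[[recipientGroup]]
  if (is.null(mel) || !length(mel))
    stop("the '", recipientGroup, "' panel is empty")
  donors <- setdiff(names(panel@groups), recipientGroup)
  if (!length(donors)) stop("at least one donor panel is required")
  out <- do.call(rbind, lapply(donors, function(d) {
    grid <- expand.grid(p1 = mel, p3 = panel@groups[[d]],
                        stringsAsFactors = FALSE)
    if (!nrow(grid)) return(NULL)
    data.frame(p1 = grid$p1, p2 = focal, p3 = grid$p3, donor = d)
  }))
  rownames(out) <- NULL
  out
}

# Internal: deterministic partner for the f denominator's P2 slot — the
# lexicographically next donor colony after p3 (wrapping), or p3 itself when
# the donor panel holds a single colony (flagged upstream as upward-biased).
.fPartner <- function(p3, donorPanel) {
  donorPanel <- sort(donorPanel)
  if (length(donorPanel) == 1L) return(p3)
  i <- match(p3, donorPanel)
  donorPanel[if (i == length(donorPanel)) 1L else i + 1L]
}

#' Run the trio battery for one focal colony
#'
#' Computes every enumerated ABBA BABA test for a focal colony against the
#' reference panels: per test, Patterson's D with block-jackknife Z and
#' two-sided p, and the f admixture proportion using a deterministically
#' paired second donor colony in the denominator's P2 slot.  Per donor
#' subspecies the tests are aggregated (mean and SD of f, test count) and
#' classified by the all-combinations rule of [classifySignificance()].
#' Tests whose statistic is undefined are recorded with \code{NA} and a
#' warning rather than aborting the battery.
#'
#' @param freqs a polarized \linkS4class{FrequencyMatrix} (or plain matrix of
#'   polarized frequencies) whose columns cover the focal and all reference
#'   colonies; see [polarizeFrequencies()].
#' @param focal focal colony id (P2).
#' @param panel a \linkS4class{ReferencePanel}.
#' @param nBlocks jackknife blocks per test (default 20).
#' @param alpha significance level for the classification (default 0.05).
#' @param recipientGroup name of the P1 group (default \code{"mellifera"}).
#' @return a \linkS4class{BatterySummary}.  Negative mean f is reported
#'   as-is with a warning, never truncated.
#' @export
runBattery <- function(freqs, focal, panel, nBlocks = 20L, alpha = 0.05,
                       recipientGroup = "mellifera") {
  tests <- enumerateTrios(focal, panel, recipientGroup)
  f <- if (is(freqs, "FrequencyMatrix")) alleleFreq(freqs) else
    as.matrix(freqs)
  missing <- setdiff(unique(c(tests$p1, focal, tests$p3)), colnames(f))
  if (length(missing))
    stop("no frequencies for colonies: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    p3a <- .fPartner(tests$p3[i], panel@groups[[tests$donor[i]]])
    res <- tryCatch({
      trio <- makeTrio(f, tests$p1[i], focal, tests$p3[i], p3a = p3a,
                       nBlocks = nBlocks)
      suppressWarnings(
        dstatTest(trio, labels = c(P1 = tests$p1[i], P2 = focal,
                                   P3 = tests$p3[i])))
    }, error = function(e) e)
    if (is(res, "error")) {
      warning("test ", tests$p1[i], "/", tests$p3[i], " failed: ",
              conditionMessage(res))
      data.frame(p1 = tests$p1[i], p3 = tests$p3[i], p3a = p3a,
                 donor = tests$donor[i], D = NA_real_, Z = NA_real_,
                 pValue = NA_real_, f = NA_real_)
    } else {
      data.frame(p1 = tests$p1[i], p3 = tests$p3[i], p3a = p3a,
                 donor = tests$donor[i], D = res@D, Z = res@Z,
                 pValue = res@pValue, f = res@f)
    }
  })
  testDF <- do.call(rbind, rows)
  if (any(testDF$p3a == testDF$p3))
    warning("donor panel(s) with a single colony: the same representative ",
            "fills both f slots, which biases f upward")
  summ <- do.call(rbind, lapply(split(testDF, testDF$donor), function(d) {
    data.frame(donor = d$donor[1L],
               meanF = mean(d$f, na.rm = TRUE),
               sdF = if (nrow(d) > 1L) sd(d$f, na.rm = TRUE) else 0,
               nTests = nrow(d),
               class = classifySignificance(d, alpha = alpha))
  }))
  rownames(summ) <- NULL
  if (any(summ$meanF < 0, na.rm = TRUE))
    warning("negative mean f reported as-is for donor(s): ",
            paste(summ$donor[summ$meanF < 0], collapse = ", "))
  new("BatterySummary", focal = focal, tests = testDF, summary = summ,
      nBlocks = as.integer(nBlocks), alpha = alpha)
}

#' All-combinations significance classification
#'
#' A focal colony is classified \code{"significant"} for a donor subspecies
#' only if every test in the donor group shows D > 0 with p below the
#' significance level, regardless of which colonies represented the
#' standards; any failing (or undefined) test yields \code{"nsi"} — no
#' significant introgression.
#'
#' @param tests a data.frame of test results for one donor group, with
#'   columns \code{D} and \code{pValue}.
#' @param alpha significance level (default 0.05).
#' @return \code{"significant"} or \code{"nsi"}.
#' @examples
#' classifySignificance(data.frame(D = c(0.1, 0.2), pValue = c(0.01, 0.03)))
#' classifySignificance(data.frame(D = c(0.1, 0.2), pValue = c(0.01, 0.06)))
#' @export
classifySignificance <- function(tests, alpha = 0.05) {
  if (nrow(tests) < 1L) stop("at least one test result is required")
  ok <- tests$D > 0 & tests$pValue < alpha
  if (all(!is.na(ok)) && all(ok)) "significant" else "nsi"
}
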