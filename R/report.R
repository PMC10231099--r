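#' Assemble the cross-method comparison table
#'
#' Joins the trio-battery f estimates (per donor subspecies, with the
#' all-combinations "nsi" classification) to ancestry membership Q values
#' from any number of genotyping approaches, one row per colony.  Colonies
#' absent from an input are marked \code{"no sample"}, which is never
#' conflated with \code{"nsi"} (tested but not significant).  Values are
#' kept at full precision; presentation rounding is left to
#' [formatSummary()].
#'
#' @param batteries a list of \linkS4class{BatterySummary} objects (one per
#'   focal colony), or \code{NULL} for a Q-only table.
#' @param qTables named list of data.frames, each with columns \code{colony}
#'   and \code{q}; names become the Q columns of the output.
#' @return a data.frame with one row per colony: \code{colony}, one
#'   \code{f_<donor>} and \code{class_<donor>} column pair per donor
#'   subspecies, and one column per Q table.  Duplicate colony ids in any
#'   input raise an error.
#' @export
buildSummary <- function(batteries = NULL, qTables = list()) {
  colonies <- character(0)
  fWide <- NULL
  if (length(batteries)) {
    ids <- vapply(batteries, function(b) b@focal, "")
    if (any(duplicated(ids))) stop("duplicate focal colony ids")
    rows <- lapply(batteries, function(b) {
      s <- b@summary
      out <- data.frame(colony = b@focal)
      for (i in seq_len(nrow(s))) {
        out[[paste0("f_", s$donor[i])]] <- s$meanF[i]
        out[[paste0("class_", s$donor[i])]] <- s$class[i]
      }
      out
    })
    fWide <- do.call(rbind, rows)
    colonies <- fWide$colony
  }
  for (nm in names(qTables)) {
    qt <- qTables[[nm]]
    if (any(duplicated(qt$colony)))
      stop("duplicate colony ids in Q table '", nm, "'")
    colonies <- union(colonies, qt$colony)
  }
  out <- data.frame(colony = colonies)
  if (!is.null(fWide))
    out <- merge(out, fWide, by = "colony", all.x = TRUE, sort = FALSE)
  for (nm in names(qTables)) {
    qt <- qTables[[nm]][, c("colony", "q")]
    colnames(qt)[2L] <- nm
    out <- merge(out, qt, by = "colony", all.x = TRUE, sort = FALSE)
  }
  out[order(out$colony), , drop = FALSE]
}

#' Render a comparison table for presentation
#'
#' Formats a [buildSummary()] table the way such summaries are printed:
#' f estimates replaced by \code{"nsi"} where the donor classification was
#' not significant, absent entries shown as \code{"no sample"}, and numbers
#' rounded (default 3 decimal places for f, 2 for Q).
#'
#' @param summary a data.frame from [buildSummary()].
#' @param fDigits,qDigits rounding for f and Q columns.
#' @return a character data.frame ready for printing or TSV export.
#' @export
formatSummary <- function(summary, fDigits = 3L, qDigits = 2L) {
  out <- data.frame(colony = summary$colony)
  fCols <- grep("^f_", colnames(summary), value = TRUE)
  for (fc in fCols) {
    cc <- sub("^f_", "class_", fc)
    val <- ifelse(is.na(summary[[fc]]), "no sample",
                  ifelse(!is.na(summary[[cc]]) & summary[[cc]] == "nsi",
                         "nsi", sprintf("%.*f", fDigits, summary[[fc]])))
    out[[fc]] <- val
  }
  qCols <- setdiff(colnames(summary), c("colony", fCols,
                                        sub("^f_", "class_", fCols)))
  for (qc in qCols)
    out[[qc]] <- ifelse(is.na(summary[[qc]]), "no sample",
                        sprintf("%.*f", qDigits, summary[[qc]]))
  out
}

#' Squared Pearson correlation between two methods
#'
#' The R-squared used to compare per-colony introgression estimates between
#' genotyping approaches: the squared Pearson correlation over pairwise
#' complete values.  Sign-blind by construction.
#'
#' @param x,y paired per-colony values; at least 3 complete pairs required.
#' @return R-squared in [0, 1].
#' @examples
#' correlateMethods(1:5, c(1.1, 2.0, 2.9, 4.2, 5.1))
#' @export
correlateMethods <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("at least 3 paired non-missing values are required")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    stop("zero variance: correlation undefined")
  cor(x[ok], y[ok])^2
}

#' Mean ancestry membership across colonies
#'
#' Arithmetic mean of per-colony Q values at full precision; rounding (to
#' the 2 decimal places such tables print) is presentation only.
#'
#' @param values numeric Q values, possibly with \code{NA}.
#' @param digits optional rounding for presentation; \code{NULL} (default)
#'   returns full precision.
#' @return the mean.
#' @export
meanQ <- function(values, digits = NULL) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing values")
  m <- mean(v)
  if (is.null(digits)) m else round(m, digits)
}

#' Bundled colony survey summaries
#'
#' Two small plain-text tables bundled with the package summarize a survey
#' of putative \emph{A. m. mellifera} colonies from South West England
#' assessed for C-lineage introgression by three genotyping approaches.
#' \code{swColonyQ()} returns K = 2 ancestry membership (Q) values for the
#' 17 colonies common to all three approaches (SNP array, individual
#' RAD-seq, pooled colony RAD-seq; columns \code{*_M}, \code{*_C}).
#' \code{swColonySummary()} returns the per-colony comparison of pooled
#' ABBA BABA f estimates per donor subspecies (with \code{"nsi"} marking
#' colonies not significant in all trio combinations and \code{"no sample"}
#' marking colonies absent from an approach) against the C-lineage Q values
#' of each approach.  These tables drive the worked examples and the
#' reproduction script.
#'
#' @return a data.frame (see Details).
#' @examples
#' q <- swColonyQ()
#' meanQ(q$pool_M, digits = 2)
#' @export
swColonyQ <- function() {
  read.delim(system.file("extdata", "sw_colony_qvalues.tsv",
                         package = "beeIntrogress"),
             stringsAsFactors = FALSE)
}

#' @rdname swColonyQ
#' @export
swColonySummary <- function() {
  read.delim(system.file("extdata", "sw_colony_introgression.tsv",
                         package = "beeIntrogress"),
             stringsAsFactors = FALSE, na.strings = "no sample")
}

#' Count colonies by significance pattern
#'
#' Applies the all-combinations reading of the trio battery to a comparison
#' table whose pooled f columns carry \code{"nsi"} tokens: counts colonies
#' not significant for both donor subspecies, and those not significant for
#' exactly one.
#'
#' @param summary a data.frame with columns \code{f_ligustica} and
#'   \code{f_carnica} holding numbers or the token \code{"nsi"} (\code{NA}
#'   for colonies without a pooled sample).
#' @return named integer vector: \code{bothNsi}, \code{carnicaOnly},
#'   \code{ligusticaOnly}, \code{tested}.
#' @export
countNsi <- function(summary) {
  lig <- summary$f_ligustica
  car <- summary$f_carnica
  tested <- !is.na(lig) & !is.na(car)
  ligNsi <- tested & lig == "nsi"
  carNsi <- tested & car == "nsi"
  c(bothNsi = sum(ligNsi & carNsi),
    carnicaOnly = sum(carNsi & !ligNsi),
    ligusticaOnly = sum(ligNsi & !carNsi),
    tested = sum(tested))
}
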