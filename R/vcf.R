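#' Write site-by-sample data as VCF 4.2
#'
#' Writes a \linkS4class{GenotypeMatrix} (FORMAT GT; dosage 0/1/2 encoded as
#' \code{0/0}, \code{0/1}, \code{1/1}, missing as \code{./.}) or a
#' \linkS4class{PoolCounts} (FORMAT AD as comma-separated ref,alt supporting
#' reads plus DP) through \pkg{vcfR}.  The header declares the contigs and
#' FORMAT definitions; output is gzip-compressed VCF, which [readVCF()]
#' round-trips losslessly.  An object with zero samples yields a valid
#' header-plus-sites VCF without FORMAT columns.
#'
#' @param x a \linkS4class{GenotypeMatrix} or \linkS4class{PoolCounts}.
#' @param path output file path (conventionally ending in \code{.vcf.gz}).
#' @return \code{path}, invisibly.
#' @seealso [readVCF()]
#' @export
setGeneric("writeVCF", function(x, path) standardGeneric("writeVCF"))

.vcfFix <- function(x) {
  gr <- rowRanges(x)
  fix <- cbind(CHROM = as.character(seqnames(gr)),
               POS = as.character(BiocGenerics::start(gr)),
               ID = ".",
               REF = as.character(rowData(x)$ref),
               ALT = as.character(rowData(x)$alt),
               QUAL = ".", FILTER = "PASS", INFO = ".")
  fix
}

.vcfMeta <- function(x, formats) {
  contigs <- unique(as.character(seqnames(rowRanges(x))))
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ">"),
    formats)
}

.writeVcfR <- function(meta, fix, gt, path) {
  if (is.null(gt) || ncol(gt) == 0L) {
    # vcfR drops fix-only records on write; emit the sites block directly
    con <- gzfile(path, "w")
    on.exit(close(con))
    writeLines(meta, con)
    writeLines(paste0("#", paste(colnames(fix), collapse = "\t")), con)
    if (nrow(fix))
      writeLines(apply(fix, 1L, paste, collapse = "\t"), con)
  } else {
    v <- new(getClass("vcfR", where = asNamespace("vcfR")),
             meta = meta, fix = fix, gt = gt)
    vcfR::write.vcf(v, file = path)
  }
  invisible(path)
}

#' @rdname writeVCF
#' @export
setMethod("writeVCF", "GenotypeMatrix", function(x, path) {
  gt <- NULL
  if (ncol(x)) {
    g <- dosage(x)
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
    gt[is.na(g)] <- "./."
    gt <- cbind(FORMAT = "GT", gt)
    colnames(gt) <- c("FORMAT", colnames(x))
  }
  meta <- .vcfMeta(x, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  .writeVcfR(meta, .vcfFix(x), gt, path)
})

#' @rdname writeVCF
#' @export
setMethod("writeVCF", "PoolCounts", function(x, path) {
  gt <- NULL
  if (ncol(x)) {
    ad <- alleleDepth(x)
    gt <- matrix(paste0(ad$ref, ",", ad$alt, ":", poolDepth(x)),
                 nrow = nrow(x))
    gt <- cbind(FORMAT = "AD:DP", gt)
    colnames(gt) <- c("FORMAT", colnames(x))
  }
  meta <- .vcfMeta(x, c(
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"))
  .writeVcfR(meta, .vcfFix(x), gt, path)
})

#' Read a VCF into a site-by-sample container
#'
#' Reads VCF 4.x through \pkg{vcfR}.  In \code{"genotype"} mode, per-sample GT
#' fields are converted to diploid derived-allele dosages (phased or unphased
#' separators accepted; anything containing \code{.} becomes \code{NA}); when
#' a DP FORMAT field is present it is attached as an additional assay so that
#' depth filters apply.  In \code{"pool"} mode, AD and DP fields are parsed
#' into supporting-read count matrices.
#'
#' @param path a VCF file (plain or gzip).
#' @param mode \code{"genotype"} or \code{"pool"}.
#' @return a \linkS4class{GenotypeMatrix} or \linkS4class{PoolCounts};
#'   multiallelic records (comma in ALT) are kept as-is and should be removed
#'   with [filterBiallelic()].
#' @seealso [writeVCF()], [filterBiallelic()]
#' @export
readVCF <- function(path, mode = c("genotype", "pool")) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  sites <- .siteRanges(chrom, pos, ref, alt)
  nSamp <- max(0L, ncol(v@gt) - 1L)
  if (nSamp == 0L) {
    empty <- matrix(integer(0), nrow = length(sites), ncol = 0L)
    if (mode == "pool")
      return(.newSiteExperiment("PoolCounts",
        list(adRef = empty, adAlt = empty, dp = empty), sites, character(0)))
    return(.newSiteExperiment("GenotypeMatrix", list(dosage = empty),
                              sites, character(0)))
  }
  if (mode == "pool") {
    ad <- vcfR::extract.gt(v, element = "AD")
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    adRef <- apply(ad, 2L, function(s)
      as.integer(vapply(strsplit(s, ","), `[`, "", 1L)))
    adAlt <- apply(ad, 2L, function(s)
      as.integer(vapply(strsplit(s, ","), `[`, "", 2L)))
    storage.mode(dp) <- "integer"
    return(.newSiteExperiment("PoolCounts",
      list(adRef = adRef, adAlt = adAlt, dp = dp), sites, colnames(ad)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count1 <- function(s) {
    al <- strsplit(gsub("\\|", "/", s), "/")
    vapply(al, function(a) {
      if (any(a == ".") || anyNA(a)) NA_integer_
      else sum(as.integer(a) > 0L)
    }, integer(1L))
  }
  g <- apply(gt, 2L, count1)
  g <- matrix(g, nrow = nrow(gt), dimnames = dimnames(gt))
  assays <- list(dosage = g)
  dp <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  if (!is.null(dp) && !all(is.na(dp))) {
    storage.mode(dp) <- "integer"
    assays$dp <- dp
  }
  .newSiteExperiment("GenotypeMatrix", assays, sites, colnames(gt))
}
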