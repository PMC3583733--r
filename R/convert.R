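# Converters from standard variant-call outputs (VCF, Complete Genomics var
# files) to the three-column profile TSV. Only single-base substitutions on
# the Y chromosome are kept; everything else is counted, never fatal.

.isYChrom <- function(x) tolower(x) %in% c("y", "chry", "24")

#' Conversion bookkeeping
#'
#' Every input record is classified exactly once:
#' `nInput = nKept + nNonY + nNonSnp`. The non-SNP bucket also covers
#' records excluded on genotype grounds (heterozygous calls on the haploid
#' Y, homozygous-reference records, missing genotypes), each of which is
#' flagged with a warning.
#'
#' @param nInput,nKept,nNonY,nNonSnp record counts.
#' @return a classed list of the four counts.
#' @export
ConversionStats <- function(nInput, nKept, nNonY, nNonSnp) {
  stopifnot(nInput == nKept + nNonY + nNonSnp)
  structure(list(nInput = as.integer(nInput), nKept = as.integer(nKept),
                 nNonY = as.integer(nNonY), nNonSnp = as.integer(nNonSnp)),
            class = "ConversionStats")
}

#' @export
print.ConversionStats <- function(x, ...) {
  cat("records:", x$nInput, "| Y SNPs kept:", x$nKept,
      "| non-Y skipped:", x$nNonY, "| non-SNP skipped:", x$nNonSnp, "\n")
  invisible(x)
}

#' Convert a VCF into a SNP calling profile
#'
#' Keeps records where CHROM is the Y chromosome (`Y`/`chrY`/`24`,
#' case-insensitive), REF and the genotype-selected ALT are single bases,
#' and the genotype carries the alternate allele (haploid or homozygous
#' alternate). Heterozygous genotypes — artifacts on the haploid Y — are
#' skipped with a warning, as are homozygous-reference and missing
#' genotypes. Multi-allelic records use the first ALT present in the
#' genotype (with a warning). A VCF without genotype columns is treated as a
#' site list: every Y SNP record is kept.
#'
#' @param path VCF file (plain or bgzipped).
#' @param build `"hg18"` or `"hg19"`.
#' @param sample sample column to use; default the first.
#' @return `list(profile = SnpProfile, stats = ConversionStats)`.
#' @export
convertVcf <- function(path, build, sample = NULL) {
  build <- match.arg(build, c("hg18", "hg19"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))   # single record drops to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- if (is.null(fix)) 0L else nrow(fix)
  if (n == 0L) {
    return(list(profile = SnpProfile(data.frame(), build, "vcf"),
                stats = ConversionStats(0L, 0L, 0L, 0L)))
  }
  gt <- NULL
  if (ncol(vcf@gt) >= 2L) {
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    cols <- colnames(gtm)
    col <- if (is.null(sample)) 1L else match(sample, cols)
    if (is.na(col)) stop("sample '", sample, "' not in VCF (",
                         paste(cols, collapse = ", "), ")")
    gt <- gtm[, col]
  }
  nNonY <- nNonSnp <- 0L
  kept <- vector("list", n)
  nHet <- nHomRef <- nMulti <- 0L
  for (i in seq_len(n)) {
    if (!.isYChrom(fix[i, "CHROM"])) { nNonY <- nNonY + 1L; next }
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    codes <- "1"
    if (!is.null(gt)) {
      g <- gt[i]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) { nNonSnp <- nNonSnp + 1L; next }
      codes <- setdiff(strsplit(g, "[/|]")[[1]], ".")
      if (length(codes) == 0L) { nNonSnp <- nNonSnp + 1L; next }
      codes <- unique(codes)
      if (length(codes) > 1L) {       # heterozygous on the haploid Y
        nHet <- nHet + 1L; nNonSnp <- nNonSnp + 1L; next
      }
      if (codes == "0") { nHomRef <- nHomRef + 1L; nNonSnp <- nNonSnp + 1L; next }
    }
    k <- suppressWarnings(as.integer(codes[1L]))
    if (is.na(k) || k < 1L || k > length(alts)) { nNonSnp <- nNonSnp + 1L; next }
    if (length(alts) > 1L) nMulti <- nMulti + 1L
    obs <- alts[k]
    if (!.isSnpAllele(ref) || !.isSnpAllele(obs)) { nNonSnp <- nNonSnp + 1L; next }
    kept[[i]] <- data.frame(position = as.integer(fix[i, "POS"]),
                            ref_allele = ref, obs_allele = obs,
                            stringsAsFactors = FALSE)
  }
  if (nHet) warning(nHet, " heterozygous genotype(s) on the haploid Y skipped")
  if (nHomRef) warning(nHomRef, " homozygous-reference record(s) skipped")
  if (nMulti) warning(nMulti, " multi-allelic record(s): used the ALT ",
                      "carried by the genotype")
  calls <- do.call(rbind, kept[!vapply(kept, is.null, TRUE)])
  if (is.null(calls)) calls <- data.frame()
  nKept <- if (nrow(as.data.frame(calls))) nrow(calls) else 0L
  sampleId <- if (!is.null(sample)) sample else
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  list(profile = SnpProfile(calls, build, sampleId),
       stats = ConversionStats(n, nKept, nNonY, nNonSnp))
}

#' Convert a Complete Genomics var file into a SNP calling profile
#'
#' Targets the tab-separated `var` column dialect with at least the columns
#' `chromosome`, `begin`, `end`, `varType`, `reference`, `alleleSeq`;
#' metadata lines starting with `#` and a leading `>` on the header line are
#' tolerated. Coordinates are 0-based half-open, so a one-base substitution
#' with `begin = b` is emitted at 1-based `position = b + 1 = end`. Only
#' rows with `varType == "snp"` on the Y chromosome become calls.
#'
#' @param path var file path.
#' @param build `"hg18"` or `"hg19"`.
#' @return `list(profile = SnpProfile, stats = ConversionStats)`.
#' @export
convertCga <- function(path, build) {
  build <- match.arg(build, c("hg18", "hg19"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(list(profile = SnpProfile(data.frame(), build, "cga"),
                stats = ConversionStats(0L, 0L, 0L, 0L)))
  }
  header <- sub("^>", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  need <- c("chromosome", "begin", "end", "varType", "reference", "alleleSeq")
  if (!all(need %in% cols))
    stop("unrecognised var-file layout; expected tab-separated columns: ",
         paste(need, collapse = ", "), " — got: ",
         paste(cols, collapse = ", "))
  body <- lines[-1L]
  n <- length(body)
  nNonY <- nNonSnp <- 0L
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    row <- setNames(as.list(f[seq_along(cols)]), cols)
    if (!.isYChrom(row$chromosome %||% "")) { nNonY <- nNonY + 1L; next }
    ref <- toupper(row$reference %||% "")
    obs <- toupper(row$alleleSeq %||% "")
    if (!identical(row$varType, "snp") ||
        !.isSnpAllele(ref) || !.isSnpAllele(obs)) {
      nNonSnp <- nNonSnp + 1L; next
    }
    kept[[i]] <- data.frame(position = as.integer(row$end),
                            ref_allele = ref, obs_allele = obs,
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, kept[!vapply(kept, is.null, TRUE)])
  if (is.null(calls)) calls <- data.frame()
  nKept <- if (nrow(as.data.frame(calls))) nrow(calls) else 0L
  list(profile = SnpProfile(calls, build,
                            sub("\\.[^.]*$", "", basename(path))),
       stats = ConversionStats(n, nKept, nNonY, nNonSnp))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
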