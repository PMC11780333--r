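## VCF -> CSV conversion ---------------------------------------------------
##
## Only the GT subfield of FORMAT is consumed; QUAL, FILTER and INFO are
## ignored (variant filtering is a pre-processing step, not this
## package's job). Records are kept only when biallelic and diploid in
## every sample; the report accounts for every input record.

#' Convert a VCF file to the genotype CSV schema
#'
#' Reads a VCF (plain or gzipped), keeps biallelic diploid records, and
#' writes a genotype CSV readable by [readGenotypeCsv()]. The emitted
#' dialect is PHASED when every kept genotype uses the `|` separator
#' and UNPHASED when every kept genotype uses `/`; a VCF mixing the two
#' separators is an error (harmonize phasing upstream rather than
#' silently discarding it). A genotype containing any missing allele
#' (`.`, `.|.`, `./.`, half-calls like `./1`) is written as the
#' dialect's missing token.
#'
#' Records with more than one ALT allele or any allele index >= 2 are
#' counted `droppedMultiallelic`; genotypes with a number of allele
#' fields other than two (haploid or polyploid calls) make the record
#' `droppedNondiploid`; otherwise-unparsable genotypes count
#' `droppedOther`.
#'
#' @param vcfPath Input VCF path (`.vcf` or `.vcf.gz`).
#' @param outPath Output CSV path. Written only when at least one
#'   record is kept.
#' @param addMarkerNames If `TRUE`, marker names are generated by
#'   concatenating chromosome and position with an underscore (e.g.
#'   `Chr01_123456`); if `FALSE` the VCF ID field is used, falling back
#'   to the generated name where ID is `.`.
#' @return A [ConversionReport-class]; its counts always satisfy
#'   `kept + dropped == totalRecords`.
#' @export
#' @seealso [writeSyntheticVcf()] for the matching test-fixture writer.
convertVcf <- function(vcfPath, outPath, addMarkerNames = FALSE) {
  if (!file.exists(vcfPath)) stop("file not found: ", vcfPath, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(vcfPath, verbose = FALSE),
                  error = function(e)
                    stop("unreadable VCF: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2)
    stop("VCF has no sample genotype columns", call. = FALSE)
  if (!any(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"])))
    stop("VCF FORMAT has no GT field", call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcf@fix
  n <- nrow(fix)
  sampleNames <- colnames(gt)

  isMissing <- function(tok) is.na(tok) | grepl("\\.", tok)
  sepCount <- function(tok)
    lengths(regmatches(tok, gregexpr("[|/]", tok)))

  status <- character(n)
  for (i in seq_len(n)) {
    toks <- gt[i, ]
    nonmiss <- toks[!is.na(toks) & toks != "."]
    seps <- sepCount(nonmiss)
    alt <- fix[i, "ALT"]
    if ((!is.na(alt) && grepl(",", alt, fixed = TRUE)) ||
        any(grepl("[2-9]", nonmiss) & grepl("^[0-9.|/]+$", nonmiss))) {
      status[i] <- "multiallelic"
    } else if (any(seps != 1L)) {
      status[i] <- "nondiploid"
    } else if (!all(grepl("^[01.][|/][01.]$", nonmiss))) {
      status[i] <- "other"
    } else {
      status[i] <- "kept"
    }
  }

  keep <- status == "kept"
  report <- function(dialectName) new(
    "ConversionReport",
    totalRecords = n, kept = sum(keep),
    droppedMultiallelic = sum(status == "multiallelic"),
    droppedNondiploid = sum(status == "nondiploid"),
    droppedOther = sum(status == "other"),
    dialect = dialectName)

  if (!any(keep)) return(report(NA_character_))

  keptGt <- gt[keep, , drop = FALSE]
  nonmiss <- keptGt[!isMissing(keptGt)]
  hasPipe <- any(grepl("|", nonmiss, fixed = TRUE))
  hasSlash <- any(grepl("/", nonmiss, fixed = TRUE))
  if (hasPipe && hasSlash)
    stop(paste("VCF mixes phased ('|') and unphased ('/') genotype separators;",
               "harmonize phasing (e.g. re-phase or strip phase) before converting"),
         call. = FALSE)
  dialectName <- if (hasPipe || !hasSlash) "PHASED" else "UNPHASED"

  chrom <- fix[keep, "CHROM"]
  pos <- fix[keep, "POS"]
  generated <- paste(chrom, pos, sep = "_")
  if (addMarkerNames) {
    name <- generated
  } else {
    id <- fix[keep, "ID"]
    name <- ifelse(is.na(id) | id == ".", generated, id)
  }
  name <- make.unique(name, sep = "_dup")

  toks <- keptGt
  toks[isMissing(toks)] <- missingToken(dialectName)
  out <- data.frame(chrom = chrom, marker = name, pos = as.integer(pos),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(toks, check.names = FALSE,
                                  stringsAsFactors = FALSE))
  utils::write.csv(out, outPath, row.names = FALSE, quote = FALSE)
  report(dialectName)
}
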