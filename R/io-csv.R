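## CSV genotype tables -----------------------------------------------------
##
## Schema: a header row, then one row per marker. Leading metadata
## columns are either 3 (chromosome, marker name, physical position) or
## 4 (chromosome, marker name, genetic position, physical position);
## all later columns are samples, one per column, holding genotype
## tokens in a single dialect.

looksLikePos <- function(h) grepl("pos|bp|physic", h, ignore.case = TRUE)
looksLikeGenetic <- function(h) grepl("gen|cm|map", h, ignore.case = TRUE)

## D1: the leading-column layout is ambiguous in the wild; auto-detect
## 3 vs 4 metadata columns from header names, overridable.
detectMetaCols <- function(headers) {
  if (length(headers) >= 4 &&
      looksLikeGenetic(headers[3]) && looksLikePos(headers[4]))
    return(4L)
  3L
}

#' Read a genotype table from CSV
#'
#' Reads the comma-separated genotype schema: leading metadata columns
#' (chromosome, marker name, physical position in bp, with an optional
#' genetic-position column auto-detected from header names), then one
#' column per sample. The encoding dialect is auto-detected from the
#' cell tokens unless overridden. The returned table is normalized
#' (markers sorted by chromosome and position) with a validation report
#' in its metadata.
#'
#' @param path CSV file path.
#' @param dialect Optional explicit dialect override (see
#'   [listDialects()]); by default detected with [detectDialect()].
#' @param metaCols Optional explicit number of leading metadata columns
#'   (3 or 4); by default detected from header names.
#' @return A [GenotypeTable-class].
#' @export
#' @seealso [writeGenotypeCsv()], [convertVcf()]
readGenotypeCsv <- function(path, dialect = NULL, metaCols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (ncol(raw) < 3)
    stop("expected at least 3 leading metadata columns (chromosome, marker, position)",
         call. = FALSE)
  headers <- colnames(raw)
  if (suppressWarnings(!is.na(as.numeric(headers[3]))) ||
      suppressWarnings(!is.na(as.numeric(headers[min(4, length(headers))]))))
    stop("input appears to lack a header row (numeric column names found)",
         call. = FALSE)
  if (is.null(metaCols)) metaCols <- detectMetaCols(headers)
  if (!metaCols %in% c(3L, 4L)) stop("metaCols must be 3 or 4", call. = FALSE)
  if (ncol(raw) <= metaCols)
    stop("no sample columns: the file holds only marker metadata", call. = FALSE)
  if (nrow(raw) == 0) stop("no marker rows in ", path, call. = FALSE)

  posCol <- metaCols  # physical position is the last metadata column
  pos <- suppressWarnings(as.numeric(raw[[posCol]]))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0)
    stop(sprintf("non-integer position '%s' at row %d, column %d ('%s')",
                 raw[[posCol]][bad[1]], bad[1] + 1L, posCol, headers[posCol]),
         call. = FALSE)

  mk <- data.frame(chrom = raw[[1]], name = raw[[2]], pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  if (metaCols == 4L)
    mk$genpos <- suppressWarnings(as.numeric(raw[[3]]))

  samples <- headers[(metaCols + 1L):ncol(raw)]
  gmat <- as.matrix(raw[, (metaCols + 1L):ncol(raw), drop = FALSE])
  tokens <- as.vector(gmat)
  if (is.null(dialect)) dialect <- detectDialect(tokens)
  dialect <- match.arg(dialect, listDialects())

  where <- as.vector(outer(seq_len(nrow(gmat)), seq_len(ncol(gmat)),
                           function(i, j)
                             sprintf("row %d, column %d ('%s')",
                                     i + 1L, j + metaCols, samples[j])))
  codes <- parseTokens(tokens, dialect, where = where)
  h1 <- matrix(codes$h1, nrow = nrow(gmat))
  h2 <- matrix(codes$h2, nrow = nrow(gmat))
  normalizeTable(GenotypeTable(mk, samples, h1, h2, dialect))
}

#' Write a genotype table to CSV
#'
#' Inverse of [readGenotypeCsv()] up to heterozygote canonicalization:
#' reading the written file reproduces the table, with phased token
#' order preserved exactly and unphased heterozygotes in canonical
#' `0/1` form.
#'
#' @param x A [GenotypeTable-class] with at least one marker.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeGenotypeCsv <- function(x, path) {
  stopifnot(is(x, "GenotypeTable"))
  if (nrow(x@markers) == 0)
    stop("refusing to write a table with zero markers", call. = FALSE)
  tok <- matrix(serializeCodes(as.vector(x@hap1), as.vector(x@hap2),
                               x@dialect),
                nrow = nrow(x@markers),
                dimnames = list(NULL, x@samples))
  out <- data.frame(chrom = x@markers$chrom, marker = x@markers$name,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if ("genpos" %in% colnames(x@markers)) out$genetic_pos <- x@markers$genpos
  out$pos <- x@markers$pos
  out <- cbind(out, as.data.frame(tok, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
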