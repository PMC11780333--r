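## Encoding dialects -------------------------------------------------------

#' The three genotype encoding dialects
#'
#' A genotype table cell is written in exactly one of three dialects:
#' \describe{
#'   \item{SIMPLE}{letters `A`, `B` (the two homozygotes), `H`
#'     (heterozygote) and `N` (missing); never phased.}
#'   \item{PHASED}{VCF-style `0|0`, `1|1`, `1|0`, `0|1` and missing
#'     `.|.`; allele order is haplotype order and is preserved.}
#'   \item{UNPHASED}{VCF-style `0/0`, `1/1`, `1/0`, `0/1` and missing
#'     `./.`; heterozygote order carries no information and is
#'     canonicalized to `0/1`.}
#' }
#' One dialect applies to a whole table; mixing dialects is an error.
#'
#' @return `listDialects()`: the three dialect names.
#'   `dialectTokens(dialect)`: the five tokens (four calls + one
#'   missing) of that dialect.
#' @param dialect Dialect name.
#' @export
#' @examples
#' listDialects()
#' dialectTokens("PHASED")
listDialects <- function() c("SIMPLE", "PHASED", "UNPHASED")

#' @rdname listDialects
#' @export
dialectTokens <- function(dialect) {
  switch(match.arg(dialect, listDialects()),
         SIMPLE   = c("A", "B", "H", "N"),
         PHASED   = c("0|0", "1|1", "1|0", "0|1", ".|."),
         UNPHASED = c("0/0", "1/1", "1/0", "0/1", "./."))
}

#' @rdname listDialects
#' @export
missingToken <- function(dialect) {
  switch(match.arg(dialect, listDialects()),
         SIMPLE = "N", PHASED = ".|.", UNPHASED = "./.")
}

## Internal vectorized token parser. Returns list(h1, h2) of integer
## allele codes. `where` is an optional character vector of coordinates
## ("row i, column j") used in error messages.
parseTokens <- function(tokens, dialect, where = NULL) {
  dialect <- match.arg(dialect, listDialects())
  loc <- function(i) if (is.null(where)) sprintf("token %d", i) else where[i]
  n <- length(tokens)
  h1 <- rep(NA_integer_, n); h2 <- rep(NA_integer_, n)

  ## unsupported calls are rejected with a specific message regardless
  ## of dialect: polyploid (>= 3 allele fields) and multi-allelic
  ## (allele index >= 2)
  nfields <- lengths(regmatches(tokens, gregexpr("[|/]", tokens))) + 1L
  poly <- nfields >= 3L & grepl("[|/]", tokens)
  if (any(poly))
    stop(sprintf("unsupported polyploid genotype '%s' at %s (>= 3 allele fields)",
                 tokens[which(poly)[1]], loc(which(poly)[1])), call. = FALSE)
  multi <- grepl("^[0-9.]+[|/][0-9.]+$", tokens) &
    grepl("[2-9]", tokens)
  if (any(multi))
    stop(sprintf("unsupported multi-allelic genotype '%s' at %s (allele index >= 2)",
                 tokens[which(multi)[1]], loc(which(multi)[1])), call. = FALSE)

  if (dialect == "SIMPLE") {
    map1 <- c(A = 0L, B = 1L, H = 0L)
    map2 <- c(A = 0L, B = 1L, H = 1L)
    bad <- !(tokens %in% c(names(map1), "N"))
    if (any(bad))
      stop(sprintf("token '%s' at %s is not valid in the SIMPLE dialect (expected A, B, H or N)",
                   tokens[which(bad)[1]], loc(which(bad)[1])), call. = FALSE)
    known <- tokens != "N"
    h1[known] <- map1[tokens[known]]
    h2[known] <- map2[tokens[known]]
  } else {
    sep <- if (dialect == "PHASED") "|" else "/"
    ok <- tokens %in% dialectTokens(dialect)
    if (any(!ok))
      stop(sprintf("token '%s' at %s is not valid in the %s dialect",
                   tokens[which(!ok)[1]], loc(which(!ok)[1]), dialect),
           call. = FALSE)
    known <- tokens != missingToken(dialect)
    parts <- strsplit(tokens[known], sep, fixed = TRUE)
    a <- as.integer(vapply(parts, `[`, "", 1L))
    b <- as.integer(vapply(parts, `[`, "", 2L))
    if (dialect == "UNPHASED") {   # canonicalize het order: 1/0 == 0/1
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    }
    h1[known] <- a; h2[known] <- b
  }
  list(h1 = h1, h2 = h2)
}

#' Parse a single genotype token
#'
#' Parses one cell value under a fixed dialect into a [Call-class].
#' Exactly the dialect's four call tokens and one missing token are
#' accepted; anything else errors, with specific messages for polyploid
#' (e.g. `0/0/0/1`) and multi-allelic (e.g. `0/2`) calls, which are
#' unsupported.
#'
#' @param token Non-empty genotype string.
#' @param dialect Dialect name (see [listDialects()]).
#' @return A [Call-class]; phased for the PHASED dialect only.
#' @export
#' @examples
#' parseCall("1|1", "PHASED")   # Call(B, B, phased)
#' parseCall("H", "SIMPLE")     # canonical heterozygote Call(A, B)
parseCall <- function(token, dialect) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  h <- parseTokens(token, dialect)
  st <- function(code) if (is.na(code)) "MISSING" else c("A", "B")[code + 1L]
  Call(st(h$h1), st(h$h2), phased = dialect == "PHASED")
}

#' Serialize a call back to its dialect token
#'
#' Inverse of [parseCall()] up to canonicalization: every token round
#' trips exactly, except that the unphased heterozygote serializes to
#' the canonical `0/1` (so `1/0` reads back as `0/1`).
#'
#' @param call A [Call-class].
#' @param dialect Target dialect.
#' @return The token string.
#' @export
serializeCall <- function(call, dialect) {
  code <- function(st) if (st == "MISSING") NA_integer_ else
    match(st, c("A", "B")) - 1L
  serializeCodes(code(call@hap1), code(call@hap2), dialect)
}

## vectorized serializer over allele-code vectors
serializeCodes <- function(h1, h2, dialect) {
  dialect <- match.arg(dialect, listDialects())
  out <- character(length(h1))
  miss <- is.na(h1)
  out[miss] <- missingToken(dialect)
  if (dialect == "SIMPLE") {
    out[!miss] <- ifelse(h1[!miss] != h2[!miss], "H",
                         ifelse(h1[!miss] == 0L, "A", "B"))
  } else if (dialect == "PHASED") {
    out[!miss] <- paste0(h1[!miss], "|", h2[!miss])
  } else {
    a <- pmin(h1[!miss], h2[!miss]); b <- pmax(h1[!miss], h2[!miss])
    out[!miss] <- paste0(a, "/", b)
  }
  out
}

#' Detect the encoding dialect of a set of tokens
#'
#' Returns the unique dialect whose token set covers every token in the
#' collection. Detection is order-independent. If no dialect covers the
#' tokens (e.g. a table mixing `N` and `.|.`), or the tokens are empty
#' so every dialect matches, an error asks for an explicit dialect
#' override.
#'
#' @param tokens Character vector of genotype cell values.
#' @return A dialect name.
#' @export
#' @examples
#' detectDialect(c("A", "H", "N", "B"))    # "SIMPLE"
#' detectDialect(c("0|1", "1|1", ".|."))   # "PHASED"
detectDialect <- function(tokens) {
  u <- unique(tokens[!is.na(tokens) & nzchar(tokens)])
  hits <- Filter(function(d) all(u %in% dialectTokens(d)), listDialects())
  if (length(hits) == 1L) return(hits[[1]])
  if (length(hits) > 1L)
    stop("dialect is ambiguous (no informative tokens); pass an explicit dialect override",
         call. = FALSE)
  bad <- Filter(function(t) !any(vapply(listDialects(),
                                        function(d) t %in% dialectTokens(d),
                                        TRUE)), u)
  stop(sprintf(paste0("tokens match no single dialect (e.g. %s); the three ",
                      "dialects cannot be mixed in one table; pass an explicit ",
                      "dialect override after fixing the data"),
               paste(sQuote(utils::head(if (length(bad)) bad else u, 3)),
                     collapse = ", ")), call. = FALSE)
}

## GenotypeTable -----------------------------------------------------------

#' Construct a GenotypeTable
#'
#' @param markers `data.frame` with columns `chrom`, `name`, `pos`.
#' @param samples Character vector of sample names.
#' @param hap1,hap2 Integer matrices of allele codes (0/1/NA),
#'   |markers| x |samples|.
#' @param dialect Encoding dialect of the source data.
#' @param metadata Optional list.
#' @return A validated [GenotypeTable-class].
#' @export
GenotypeTable <- function(markers, samples, hap1, hap2, dialect,
                          metadata = list()) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  dimnames(hap1) <- dimnames(hap2) <- list(markers$name, samples)
  new("GenotypeTable", markers = markers, samples = as.character(samples),
      hap1 = hap1, hap2 = hap2, dialect = dialect, metadata = metadata)
}

#' Accessors for GenotypeTable
#'
#' @param x A [GenotypeTable-class].
#' @param which Haplotype index, 1 or 2.
#' @param marker Marker name or row index.
#' @param sample Sample name or column index.
#' @return `markers()`: the marker `data.frame`; `sampleNames()`: the
#'   sample names; `dialect()`: the dialect name; `hapMatrix()`: one
#'   allele-code matrix; `callAt()`: a single [Call-class].
#' @name GenotypeTable-accessors
NULL

#' @rdname GenotypeTable-accessors
#' @export
setMethod("markers", "GenotypeTable", function(x) x@markers)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("sampleNames", "GenotypeTable", function(x) x@samples)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("dialect", "GenotypeTable", function(x) x@dialect)

#' @rdname GenotypeTable-accessors
#' @export
setMethod("hapMatrix", "GenotypeTable", function(x, which = 1L) {
  stopifnot(which %in% c(1L, 2L))
  if (which == 1L) x@hap1 else x@hap2
})

#' @rdname GenotypeTable-accessors
#' @export
setMethod("callAt", "GenotypeTable", function(x, marker, sample) {
  h1 <- x@hap1[marker, sample]; h2 <- x@hap2[marker, sample]
  st <- function(code) if (is.na(code)) "MISSING" else c("A", "B")[code + 1L]
  Call(st(h1), st(h2), phased = x@dialect == "PHASED")
})

#' Number of markers and samples
#' @param x A [GenotypeTable-class].
#' @return `dim()`: `c(markers, samples)`.
#' @export
setMethod("dim", "GenotypeTable", function(x) {
  c(nrow(x@markers), length(x@samples))
})

#' Normalize a genotype table
#'
#' Stably sorts markers by chromosome (in order of first appearance)
#' and ascending position within chromosome; markers at duplicate
#' (chromosome, position) pairs keep their input order. Attaches a
#' validation report (marker counts per chromosome) to the table
#' metadata. Idempotent. Duplicate marker or sample names are an error
#' naming the duplicates (enforced by the class validity).
#'
#' @param x A [GenotypeTable-class].
#' @return The normalized table.
#' @export
normalizeTable <- function(x) {
  stopifnot(is(x, "GenotypeTable"))
  m <- x@markers
  chromLevels <- unique(m$chrom)
  ord <- order(match(m$chrom, chromLevels), m$pos)  # radix sort: stable
  meta <- x@metadata
  counts <- table(factor(m$chrom, levels = chromLevels))
  meta$validation <- list(
    markersPerChrom = stats::setNames(as.integer(counts), names(counts)))
  GenotypeTable(m[ord, , drop = FALSE], x@samples,
                x@hap1[ord, , drop = FALSE], x@hap2[ord, , drop = FALSE],
                x@dialect, meta)
}

## show methods ------------------------------------------------------------

setMethod("show", "Call", function(object) {
  cat(sprintf("Call(%s, %s%s)\n", object@hap1, object@hap2,
              if (object@phased) ", phased" else ""))
})

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf("GenotypeTable: %d markers x %d samples [%s dialect]\n",
              nrow(object@markers), length(object@samples), object@dialect))
  counts <- table(factor(object@markers$chrom,
                         levels = unique(object@markers$chrom)))
  cat(sprintf("  chromosomes (%d): %s\n", length(counts),
              paste(sprintf("%s(%d)", names(counts), counts), collapse = " ")))
  cat(sprintf("  samples: %s\n",
              paste(utils::head(object@samples, 6), collapse = ", ")))
})

setMethod("show", "ConversionReport", function(object) {
  cat(sprintf(paste0("VCF conversion report: %d records, %d kept (%s dialect), ",
                     "%d multi-allelic, %d non-diploid, %d other dropped\n"),
              object@totalRecords, object@kept, object@dialect,
              object@droppedMultiallelic, object@droppedNondiploid,
              object@droppedOther))
})

setMethod("show", "ChromosomePaint", function(object) {
  cat(sprintf("ChromosomePaint %s (%s bp): %d + %d segments, %d ticks\n",
              object@chrom,
              format(object@length, big.mark = ",", scientific = FALSE),
              nrow(object@track1), nrow(object@track2), nrow(object@ticks)))
})

setMethod("show", "ColorSet", function(object) {
  cat(sprintf("ColorSet '%s': A=%s B=%s het=%s missing=%s\n", object@name,
              object@colors[["A"]], object@colors[["B"]],
              object@colors[["het"]], object@colors[["missing"]]))
})

setMethod("show", "FigurePlan", function(object) {
  cat(sprintf("FigurePlan [%s]%s: %d panel(s)\n", object@mode,
              if (nzchar(object@title)) paste0(" '", object@title, "'") else "",
              length(object@panels)))
})
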