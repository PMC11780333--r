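#' Scan chromosome lengths from a genome FASTA
#'
#' Reads a (plain or gzipped) FASTA file and returns, in record order,
#' the sequence length of every record: the count of sequence
#' characters excluding whitespace and line breaks. Record names are
#' the header token up to the first whitespace. This is how new
#' species' chromosome lengths enter the database (see [addSpecies()]).
#'
#' @param fastaPath FASTA file path.
#' @return Named numeric vector of lengths in bp, in record order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT toy", "ACGTA", "CGTAC"), fa)
#' scanFastaLengths(fa)   # chrT = 10
scanFastaLengths <- function(fastaPath) {
  if (!file.exists(fastaPath))
    stop("file not found: ", fastaPath, call. = FALSE)
  lens <- tryCatch(Biostrings::fasta.seqlengths(fastaPath),
                   error = function(e)
                     stop("unreadable FASTA: ", conditionMessage(e),
                          call. = FALSE))
  if (length(lens) == 0)
    stop("FASTA file has no records: ", fastaPath, call. = FALSE)
  names(lens) <- sub("\\s.*$", "", names(lens))
  if (anyDuplicated(names(lens)))
    stop("duplicate FASTA record names: ",
         paste(unique(names(lens)[duplicated(names(lens))]), collapse = ", "),
         call. = FALSE)
  stats::setNames(as.numeric(lens), names(lens))
}
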