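#' @rdname GenotypeTable-accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("dialect", function(x) standardGeneric("dialect"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("hapMatrix", function(x, which = 1L) standardGeneric("hapMatrix"))

#' @rdname GenotypeTable-accessors
#' @export
setGeneric("callAt", function(x, marker, sample) standardGeneric("callAt"))

#' @rdname ChromLengthDB-accessors
#' @export
setGeneric("speciesNames", function(db) standardGeneric("speciesNames"))

#' @rdname ChromLengthDB-accessors
#' @export
setGeneric("chromLengths", function(db, species) standardGeneric("chromLengths"))

#' @rdname addSpecies
#' @export
setGeneric("addSpecies",
           function(db, name, lengths, force = FALSE)
             standardGeneric("addSpecies"))

#' @rdname clipPaint
#' @export
setGeneric("clipPaint",
           function(paint, start, end) standardGeneric("clipPaint"))

#' @rdname paintTracks
#' @export
setGeneric("paintTracks", function(x, ...) standardGeneric("paintTracks"))
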