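## Chromosome-length database ----------------------------------------------
##
## JSON schema: { species: { chromosome: length_bp, ... }, ... }, UTF-8,
## insertion-ordered. Chromosome order in the file defines drawing
## order. The shipped default covers eight crop and model species
## (rice, sorghum, maize, bread wheat, barley, soybean, tomato,
## arabidopsis); its bp values are approximate figures taken once from
## public reference assemblies and are meant for figure scaling, not as
## an assembly-exact resource.

#' Path of the shipped chromosome-length database
#' @return File path of the packaged JSON database.
#' @export
defaultChromLengthDBPath <- function() {
  system.file("extdata", "chromosome_length_database.json",
              package = "genopaint", mustWork = TRUE)
}

#' Load a chromosome-length database from JSON
#'
#' @param path JSON file path; defaults to the packaged eight-species
#'   database.
#' @return A [ChromLengthDB-class].
#' @export
#' @examples
#' db <- loadChromLengthDB()
#' speciesNames(db)
loadChromLengthDB <- function(path = defaultChromLengthDBPath()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(sp) {
    stats::setNames(as.numeric(unlist(sp, use.names = FALSE)), names(sp))
  })
  new("ChromLengthDB", entries = entries)
}

#' Write a chromosome-length database to JSON
#'
#' @param db A [ChromLengthDB-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeChromLengthDB <- function(db, path) {
  stopifnot(is(db, "ChromLengthDB"))
  out <- lapply(db@entries, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Accessors for ChromLengthDB
#'
#' @param db A [ChromLengthDB-class].
#' @param species Species name.
#' @return `speciesNames()`: character vector of species;
#'   `chromLengths()`: named numeric vector of chromosome lengths (bp)
#'   in drawing order, erroring with the list of available species when
#'   the name is unknown.
#' @name ChromLengthDB-accessors
NULL

#' @rdname ChromLengthDB-accessors
#' @export
setMethod("speciesNames", "ChromLengthDB", function(db) names(db@entries))

#' @rdname ChromLengthDB-accessors
#' @export
setMethod("chromLengths", "ChromLengthDB", function(db, species) {
  if (!species %in% names(db@entries))
    stop(sprintf("species '%s' is not in the database; available: %s",
                 species, paste(names(db@entries), collapse = ", ")),
         call. = FALSE)
  db@entries[[species]]
})

#' Add a species to a chromosome-length database
#'
#' @param db A [ChromLengthDB-class].
#' @param name New species name (non-empty).
#' @param lengths Named numeric vector of chromosome lengths in bp,
#'   e.g. from [scanFastaLengths()]; order defines drawing order.
#' @param force Overwrite an existing species entry (default: a name
#'   collision is an error).
#' @return The updated [ChromLengthDB-class].
#' @export
#' @examples
#' db <- loadChromLengthDB()
#' db2 <- addSpecies(db, "toy_species", c(chr1 = 1000, chr2 = 500))
#' length(speciesNames(db2))   # 9
setMethod("addSpecies", "ChromLengthDB",
          function(db, name, lengths, force = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("species name must be a non-empty string", call. = FALSE)
  if (name %in% names(db@entries) && !force)
    stop(sprintf("species '%s' already exists; use force = TRUE to overwrite",
                 name), call. = FALSE)
  db@entries[[name]] <- stats::setNames(as.numeric(lengths), names(lengths))
  validObject(db)
  db
})

setMethod("show", "ChromLengthDB", function(object) {
  cat(sprintf("ChromLengthDB: %d species\n", length(object@entries)))
  for (sp in names(object@entries))
    cat(sprintf("  %s: %d chromosomes (%s bp total)\n", sp,
                length(object@entries[[sp]]),
                format(sum(object@entries[[sp]]), big.mark = ",")))
})
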