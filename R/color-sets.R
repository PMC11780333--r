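## Color sets --------------------------------------------------------------
##
## JSON schema: { set_name: { "A": "#RRGGBB", "B": "#RRGGBB",
## "het": "#RRGGBB", "missing": "#RRGGBB" }, ... }. Users add palettes
## by editing the file; every set must define all four roles.

#' Path of the shipped color-set file
#' @return File path of the packaged `color_set.json`.
#' @export
defaultColorSetPath <- function() {
  system.file("extdata", "color_set.json", package = "genopaint",
              mustWork = TRUE)
}

#' Load color sets from JSON
#'
#' @param path JSON file path; defaults to the packaged registry, which
#'   includes at least the sets `"normal"` and `"Aqua"`.
#' @return Named list of [ColorSet-class] objects.
#' @export
#' @examples
#' reg <- loadColorSets()
#' names(reg)
loadColorSets <- function(path = defaultColorSetPath()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) stop("no color sets defined in ", path, call. = FALSE)
  sets <- lapply(names(raw), function(nm) {
    cols <- unlist(raw[[nm]])
    new("ColorSet", name = nm, colors = cols)   # validity names missing roles
  })
  stats::setNames(sets, names(raw))
}

#' Look up a color set by name
#'
#' @param registry Named list from [loadColorSets()].
#' @param name Set name.
#' @return The [ColorSet-class]; unknown names error listing the
#'   available sets.
#' @export
getColorSet <- function(registry, name) {
  if (!name %in% names(registry))
    stop(sprintf("unknown color set '%s'; available: %s", name,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  registry[[name]]
}
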