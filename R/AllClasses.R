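#' @import methods
NULL

## Allele codes used in the assay matrices: 0 = A (reference / parent-1),
## 1 = B (alternate / parent-2), NA = missing. The scalar Call API exposes
## the states by name.

#' Allele state names
#'
#' The three allele states a haplotype can carry at a marker: `"A"`
#' (reference / parent-1 allele, token `0` or letter `A`), `"B"`
#' (alternate / parent-2 allele, token `1` or letter `B`) and
#' `"MISSING"`. No other state exists.
#'
#' @return Character vector of the three state names.
#' @export
#' @examples
#' alleleStates()
alleleStates <- function() c("A", "B", "MISSING")

#' Call: a diploid genotype call
#'
#' An ordered pair of allele states plus a phased flag. If either
#' haplotype is missing both are: the missing tokens of all three
#' dialects carry no partial information.
#'
#' @slot hap1,hap2 Allele state names (see [alleleStates()]).
#' @slot phased Logical; `TRUE` only for calls parsed from the PHASED
#'   dialect, where the order of `hap1`/`hap2` is meaningful.
#'
#' @export
setClass("Call", representation(
  hap1 = "character", hap2 = "character", phased = "logical"
))

setValidity("Call", function(object) {
  st <- alleleStates()
  if (length(object@hap1) != 1L || length(object@hap2) != 1L ||
      length(object@phased) != 1L)
    return("hap1, hap2 and phased must each have length 1")
  if (!(object@hap1 %in% st) || !(object@hap2 %in% st))
    return("allele states must be one of A, B, MISSING")
  if (xor(object@hap1 == "MISSING", object@hap2 == "MISSING"))
    return("if either haplotype is MISSING, both must be MISSING")
  TRUE
})

#' Construct a Call
#'
#' @param hap1,hap2 Allele state names.
#' @param phased Logical phased flag (default `FALSE`).
#' @return A [Call-class] object.
#' @export
#' @examples
#' Call("A", "B")            # canonical unphased heterozygote
#' Call("B", "A", phased = TRUE)
Call <- function(hap1, hap2, phased = FALSE) {
  new("Call", hap1 = hap1, hap2 = hap2, phased = phased)
}

#' GenotypeTable: markers x samples diploid genotype matrix
#'
#' The central container: an ordered marker map (chromosome, marker name,
#' 1-based physical position in bp), an ordered sample list, and two
#' haplotype assay matrices holding allele codes (0 = A, 1 = B, NA =
#' missing), plus the encoding dialect the table was read in.
#'
#' @slot markers `data.frame` with columns `chrom`, `name`, `pos` (and
#'   optionally `genpos`, carried but unused by layout).
#' @slot samples Character vector of unique sample names.
#' @slot hap1,hap2 Integer matrices, one row per marker, one column per
#'   sample, values in \{0, 1, NA\}.
#' @slot dialect One of `"SIMPLE"`, `"PHASED"`, `"UNPHASED"`.
#' @slot metadata List of auxiliary information (e.g. the validation
#'   report attached by [normalizeTable()]).
#'
#' @export
setClass("GenotypeTable", representation(
  markers = "data.frame",
  samples = "character",
  hap1 = "matrix",
  hap2 = "matrix",
  dialect = "character",
  metadata = "list"
))

setValidity("GenotypeTable", function(object) {
  m <- object@markers
  if (!all(c("chrom", "name", "pos") %in% colnames(m)))
    return("markers must have columns chrom, name, pos")
  nm <- nrow(m); ns <- length(object@samples)
  if (!identical(dim(object@hap1), c(nm, ns)) ||
      !identical(dim(object@hap2), c(nm, ns)))
    return("haplotype matrices must be |markers| x |samples|")
  if (anyDuplicated(object@samples))
    return(paste("duplicate sample names:",
                 paste(unique(object@samples[duplicated(object@samples)]),
                       collapse = ", ")))
  if (anyDuplicated(m$name))
    return(paste("duplicate marker names:",
                 paste(unique(m$name[duplicated(m$name)]), collapse = ", ")))
  if (nm > 0 && (!is.numeric(m$pos) || any(is.na(m$pos)) || any(m$pos < 1)))
    return("marker positions must be integers >= 1")
  if (!(object@dialect %in% listDialects()))
    return("dialect must be one of SIMPLE, PHASED, UNPHASED")
  ok <- function(h) all(is.na(h) | h %in% c(0L, 1L))
  if (!ok(object@hap1) || !ok(object@hap2))
    return("allele codes must be 0, 1 or NA")
  if (!identical(is.na(object@hap1), is.na(object@hap2)))
    return("missingness must agree between the two haplotype matrices")
  TRUE
})

#' ChromLengthDB: species -> ordered chromosome length map
#'
#' Chromosome lengths in bp per species. Chromosome order within a
#' species is preserved from insertion and defines drawing order, so
#' e.g. `"Chr2"` precedes `"Chr10"` when the source genome listed them
#' that way.
#'
#' @slot entries Named list; each element a named numeric vector of
#'   chromosome lengths (bp, >= 1) for one species.
#'
#' @export
setClass("ChromLengthDB", representation(entries = "list"))

setValidity("ChromLengthDB", function(object) {
  e <- object@entries
  if (length(e) == 0) return(TRUE)
  if (is.null(names(e)) || any(names(e) == "") || anyDuplicated(names(e)))
    return("species names must be unique and non-empty")
  for (sp in names(e)) {
    v <- e[[sp]]
    if (!is.numeric(v) || length(v) == 0)
      return(sprintf("species '%s' has no chromosomes", sp))
    if (is.null(names(v)) || anyDuplicated(names(v)))
      return(sprintf("species '%s' has missing/duplicate chromosome names", sp))
    if (any(v < 1)) return(sprintf("species '%s' has a length < 1", sp))
  }
  TRUE
})

#' ColorSet: the four role colors of one palette
#'
#' @slot name Set name.
#' @slot colors Named character vector of `#RRGGBB` hex colors for the
#'   four roles `A`, `B`, `het`, `missing`.
#'
#' @export
setClass("ColorSet", representation(name = "character", colors = "character"))

setValidity("ColorSet", function(object) {
  roles <- c("A", "B", "het", "missing")
  missing <- setdiff(roles, names(object@colors))
  if (length(missing) > 0)
    return(sprintf("color set '%s' is missing role(s): %s",
                   object@name, paste(missing, collapse = ", ")))
  if (!all(grepl("^#[0-9A-Fa-f]{6}$", object@colors[roles])))
    return(sprintf("color set '%s' has non-#RRGGBB colors", object@name))
  TRUE
})

#' ChromosomePaint: backend-free paint plan for one chromosome
#'
#' Two haplotype tracks of colored genomic segments plus marker ticks.
#' Segment coordinates are 0-based half-open bp intervals so that, with
#' fill on, segment lengths sum exactly to the chromosome length.
#'
#' @slot chrom Chromosome name.
#' @slot length Chromosome length in bp.
#' @slot track1,track2 `data.frame`s with columns `start`, `end`
#'   (0-based half-open) and `role` (a color role string, see
#'   [assignRoles()] and [blendRole()]).
#' @slot ticks `data.frame` with columns `pos` (1-based bp) and `name`.
#'
#' @export
setClass("ChromosomePaint", representation(
  chrom = "character", length = "numeric",
  track1 = "data.frame", track2 = "data.frame", ticks = "data.frame"
))

setValidity("ChromosomePaint", function(object) {
  for (tr in list(object@track1, object@track2)) {
    if (!all(c("start", "end", "role") %in% colnames(tr)))
      return("tracks need columns start, end, role")
    if (nrow(tr) > 0) {
      if (any(tr$start < 0) || any(tr$end > object@length) ||
          any(tr$start >= tr$end))
        return("segments must satisfy 0 <= start < end <= length")
    }
  }
  TRUE
})

#' RenderConfig: the full user-visible option set
#'
#' Mirrors the command-line contract: drawing mode, coloring mode, fill,
#' color set, marker-name display, zoom region, dpi, PDF flag, species.
#'
#' @slot drawingMode `"normal"`, `"compare"` or `"zoomed"`.
#' @slot coloringMode `"2-color"` or `"3-color"`.
#' @slot fill Logical; paint inter-marker gaps (on) or marker lines only.
#' @slot colorSet Name of the color set to resolve roles through.
#' @slot displayMarkerNames Logical.
#' @slot region `list(chrom =, start =, end =)` or empty list; required
#'   (with `start < end`) when `drawingMode == "zoomed"`.
#' @slot dpi Positive integer raster resolution.
#' @slot pdf Logical; additionally export vector PDF.
#' @slot species Species name to look up in the chromosome-length DB.
#'
#' @export
setClass("RenderConfig", representation(
  drawingMode = "character", coloringMode = "character", fill = "logical",
  colorSet = "character", displayMarkerNames = "logical", region = "list",
  dpi = "numeric", pdf = "logical", species = "character"
))

setValidity("RenderConfig", function(object) {
  if (!(object@drawingMode %in% c("normal", "compare", "zoomed")))
    return("drawingMode must be normal, compare or zoomed")
  if (!(object@coloringMode %in% c("2-color", "3-color")))
    return("coloringMode must be 2-color or 3-color")
  if (object@dpi <= 0) return("dpi must be positive")
  if (object@drawingMode == "zoomed") {
    r <- object@region
    if (!all(c("chrom", "start", "end") %in% names(r)))
      return("zoomed mode requires a region with chrom, start and end")
    if (r$start >= r$end) return("zoom region must have start < end")
  }
  TRUE
})

#' Construct a RenderConfig
#'
#' @param drawingMode,coloringMode,fill,colorSet,displayMarkerNames,region,dpi,pdf,species
#'   See [RenderConfig-class]. Defaults follow the documented CLI
#'   defaults: normal mode, 2-color, fill on, color set "normal",
#'   marker names on, dpi 300, PNG only.
#' @return A validated [RenderConfig-class] object.
#' @export
#' @examples
#' renderConfig(species = "rice")
#' renderConfig(drawingMode = "zoomed", species = "rice",
#'              region = list(chrom = "chr01", start = 0, end = 1e6))
renderConfig <- function(drawingMode = "normal", coloringMode = "2-color",
                         fill = TRUE, colorSet = "normal",
                         displayMarkerNames = TRUE, region = list(),
                         dpi = 300, pdf = FALSE, species = NA_character_) {
  new("RenderConfig", drawingMode = drawingMode, coloringMode = coloringMode,
      fill = fill, colorSet = colorSet,
      displayMarkerNames = displayMarkerNames, region = region,
      dpi = dpi, pdf = pdf, species = species)
}

#' FigurePlan: everything one figure needs, backend-free
#'
#' @slot mode Drawing mode that produced the plan.
#' @slot title Figure title (the sample name in normal mode).
#' @slot panels Ordered list of panels; each panel is a
#'   `list(chrom =, length =, paints = <named list of ChromosomePaint,
#'   one per sample shown>)`.
#' @slot maxLength bp of the longest chromosome in the plan (axis scale).
#'
#' @export
setClass("FigurePlan", representation(
  mode = "character", title = "character", panels = "list",
  maxLength = "numeric"
))

#' ConversionReport: VCF -> CSV conversion accounting
#'
#' Record counts satisfying `kept + droppedMultiallelic +
#' droppedNondiploid + droppedOther == totalRecords`.
#'
#' @slot totalRecords,kept,droppedMultiallelic,droppedNondiploid,droppedOther
#'   Non-negative integer counts.
#' @slot dialect Dialect of the emitted CSV (`"PHASED"` or `"UNPHASED"`).
#'
#' @export
setClass("ConversionReport", representation(
  totalRecords = "integer", kept = "integer",
  droppedMultiallelic = "integer", droppedNondiploid = "integer",
  droppedOther = "integer", dialect = "character"
))

setValidity("ConversionReport", function(object) {
  v <- c(object@totalRecords, object@kept, object@droppedMultiallelic,
         object@droppedNondiploid, object@droppedOther)
  if (any(v < 0)) return("counts must be non-negative")
  if (object@kept + object@droppedMultiallelic + object@droppedNondiploid +
      object@droppedOther != object@totalRecords)
    return("kept + dropped counts must equal totalRecords")
  TRUE
})
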