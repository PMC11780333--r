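## Layout engine -----------------------------------------------------------
##
## Pure computation of paint plans: no graphics device is touched here.
## Coordinates: marker positions are 1-based bp; paint segments are
## 0-based half-open [start, end) so that with fill on the segment
## lengths of a track sum exactly to the chromosome length.

#' Color roles of a diploid call
#'
#' Maps a call to the color role drawn on each haplotype track.
#' Homozygotes put the same parental role on both tracks; missing calls
#' put `MISSING` on both. Heterozygotes depend on the coloring mode: in
#' 3-color mode both tracks show the dedicated `HET` role; in 2-color
#' mode each track shows its own haplotype's role, so a phased `1|0`
#' puts `B` on track 1 and `A` on track 2 — phasing is depicted
#' directly. Unphased heterozygotes are canonical `Call(A, B)`, drawn
#' as `A` over `B` by convention.
#'
#' @param call A [Call-class].
#' @param coloringMode `"2-color"` or `"3-color"`.
#' @return Character vector `c(track1 = role, track2 = role)`.
#' @export
#' @examples
#' assignRoles(Call("B", "A", phased = TRUE), "2-color")  # B over A
#' assignRoles(Call("B", "A", phased = TRUE), "3-color")  # HET, HET
assignRoles <- function(call, coloringMode = c("2-color", "3-color")) {
  coloringMode <- match.arg(coloringMode)
  code <- function(st) if (st == "MISSING") NA_integer_ else
    match(st, c("A", "B")) - 1L
  r <- assignRoleCodes(code(call@hap1), code(call@hap2), coloringMode)
  c(track1 = r$r1, track2 = r$r2)
}

## vectorized over allele-code vectors; returns list(r1, r2) of role strings
assignRoleCodes <- function(h1, h2, coloringMode) {
  roleOf <- function(h) c("A", "B")[h + 1L]
  n <- length(h1)
  r1 <- rep("MISSING", n); r2 <- rep("MISSING", n)
  known <- !is.na(h1)
  hom <- known & h1 == h2
  het <- known & h1 != h2
  r1[hom] <- roleOf(h1[hom]); r2[hom] <- roleOf(h2[hom])
  if (coloringMode == "3-color") {
    r1[het] <- "HET"; r2[het] <- "HET"
  } else {
    r1[het] <- roleOf(h1[het]); r2[het] <- roleOf(h2[het])
  }
  list(r1 = r1, r2 = r2)
}

#' Blend two colors or roles
#'
#' `blendColors()` averages two `#RRGGBB` colors per channel, rounding
#' halves up; it is commutative and `blendColors(c, c) == c`.
#' `blendRole()` combines two role strings into the role painted in the
#' gap between two adjacent markers: the shared role when equal,
#' otherwise a `blend(x,y)` role (canonically ordered) that resolves to
#' the channel mean of the two member colors.
#'
#' @param x,y Hex colors (`blendColors`) or role strings (`blendRole`).
#' @return A hex color, resp. a role string.
#' @export
#' @examples
#' blendColors("#FF0000", "#0000FF")   # "#800080"
blendColors <- function(x, y) {
  rgb1 <- grDevices::col2rgb(x); rgb2 <- grDevices::col2rgb(y)
  m <- floor((rgb1 + rgb2) / 2 + 0.5)      # ties round up
  grDevices::rgb(m[1], m[2], m[3], maxColorValue = 255)
}

#' @rdname blendColors
#' @export
blendRole <- function(x, y) {
  if (x == y) return(x)
  pair <- sort(c(x, y))
  sprintf("blend(%s,%s)", pair[1], pair[2])
}

#' Resolve a color role to its hex color
#'
#' @param role Role string: `A`, `B`, `HET`, `MISSING` or
#'   `blend(x,y)`.
#' @param colorSet A [ColorSet-class].
#' @return `#RRGGBB` hex color.
#' @export
resolveRoleColor <- function(role, colorSet) {
  base <- c(A = "A", B = "B", HET = "het", MISSING = "missing")
  if (role %in% names(base))
    return(toupper(unname(colorSet@colors[[base[[role]]]])))
  m <- regmatches(role, regexec("^blend\\((.+),(.+)\\)$", role))[[1]]
  if (length(m) != 3)
    stop("unknown color role: ", role, call. = FALSE)
  blendColors(resolveRoleColor(m[2], colorSet), resolveRoleColor(m[3], colorSet))
}

## coalesce adjacent equal-role segments and drop empty ones
coalesceSegments <- function(df) {
  df <- df[df$end > df$start, , drop = FALSE]
  if (nrow(df) <= 1) { rownames(df) <- NULL; return(df) }
  keep <- logical(nrow(df))
  keep[1] <- TRUE
  runStart <- 1
  for (i in seq_len(nrow(df))[-1]) {
    if (df$role[i] == df$role[runStart] && df$start[i] == df$end[runStart]) {
      df$end[runStart] <- df$end[i]
    } else {
      runStart <- i
      keep[i] <- TRUE
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## one track's segments under fill=on: terminal extension + per-gap rule
fillTrack <- function(roles, pos, len, gapRule = "blend") {
  n <- length(roles)
  segs <- list(data.frame(start = 0, end = pos[1], role = roles[1],
                          stringsAsFactors = FALSE))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- pos[i]; b <- pos[i + 1]
      if (b <= a) next
      if (gapRule == "blend") {
        segs[[length(segs) + 1]] <- data.frame(
          start = a, end = b, role = blendRole(roles[i], roles[i + 1]),
          stringsAsFactors = FALSE)
      } else {                       # midpoint split
        m <- floor((a + b) / 2)
        segs[[length(segs) + 1]] <- data.frame(
          start = c(a, m), end = c(m, b), role = roles[c(i, i + 1)],
          stringsAsFactors = FALSE)
      }
    }
  }
  segs[[length(segs) + 1]] <- data.frame(
    start = pos[n], end = len, role = roles[n], stringsAsFactors = FALSE)
  coalesceSegments(do.call(rbind, segs))
}

## one track under fill=off: a line of width w centered on each marker
lineTrack <- function(roles, pos, len, w) {
  start <- pmax(0, pos - floor(w / 2))
  end <- pmin(len, start + w)
  start <- pmin(start, end - 1)      # keep width >= 1 at the right edge
  data.frame(start = start, end = end, role = roles,
             stringsAsFactors = FALSE)
}

#' Default marker-line width for fill = off
#'
#' Lines one bp wide vanish at genome scale; the default width is
#' `max(1, round(length / 1000))` bp so each marker stays visible.
#'
#' @param length Chromosome length in bp.
#' @return Width in bp.
#' @export
defaultLineWidth <- function(length) max(1, round(length / 1000))

#' Compute the paint plan of one sample on one chromosome
#'
#' Turns the ordered marker calls of one sample on one chromosome into
#' a [ChromosomePaint-class]: two haplotype tracks of colored segments.
#'
#' With `fill = TRUE`, the region before the first marker and after the
#' last take the terminal markers' roles, and each inter-marker gap is
#' painted a single uniform blend of its two flanking markers' roles
#' (collapsing to the shared role when they agree, so runs of equal
#' genotype merge into solid blocks); track segments then partition
#' `[0, length)` exactly. An alternative `gapRule = "midpoint"` splits
#' each gap at its midpoint instead. With `fill = FALSE`, each marker
#' is drawn as one line segment of width `lineWidth` bp centered on its
#' position.
#'
#' A chromosome carrying zero markers is painted full-length in the
#' `MISSING` role (with a notice) rather than omitted, so compare-mode
#' alignment is preserved.
#'
#' @param x A [GenotypeTable-class].
#' @param sample Sample name.
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp (from the species database).
#' @param fill Paint inter-marker gaps (`TRUE`) or marker lines only.
#' @param coloringMode `"2-color"` or `"3-color"`.
#' @param gapRule `"blend"` (default) or `"midpoint"`.
#' @param lineWidth Marker line width in bp for `fill = FALSE`;
#'   defaults to [defaultLineWidth()].
#' @param ... Unused.
#' @return A [ChromosomePaint-class].
#' @export
setMethod("paintTracks", "GenotypeTable",
          function(x, sample, chrom, length, fill = TRUE,
                   coloringMode = "2-color", gapRule = c("blend", "midpoint"),
                   lineWidth = NULL, ...) {
  gapRule <- match.arg(gapRule)
  stopifnot(sample %in% x@samples)
  idx <- which(x@markers$chrom == chrom)
  if (base::length(idx) == 0) {
    message(sprintf("no markers on chromosome %s; painted as missing", chrom))
    full <- data.frame(start = 0, end = length, role = "MISSING",
                       stringsAsFactors = FALSE)
    return(new("ChromosomePaint", chrom = chrom, length = length,
               track1 = full, track2 = full,
               ticks = data.frame(pos = numeric(0), name = character(0))))
  }
  pos <- x@markers$pos[idx]
  over <- which(pos > length)
  if (base::length(over) > 0)
    stop(sprintf("marker '%s' at %d bp lies beyond the %s chromosome length %d bp in the species database",
                 x@markers$name[idx[over[1]]], pos[over[1]], chrom, length),
         call. = FALSE)
  r <- assignRoleCodes(x@hap1[idx, sample], x@hap2[idx, sample], coloringMode)
  if (fill) {
    t1 <- fillTrack(r$r1, pos, length, gapRule)
    t2 <- fillTrack(r$r2, pos, length, gapRule)
  } else {
    w <- if (is.null(lineWidth)) defaultLineWidth(length) else lineWidth
    t1 <- lineTrack(r$r1, pos, length, w)
    t2 <- lineTrack(r$r2, pos, length, w)
  }
  new("ChromosomePaint", chrom = chrom, length = length,
      track1 = t1, track2 = t2,
      ticks = data.frame(pos = pos, name = x@markers$name[idx],
                         stringsAsFactors = FALSE))
})

#' Clip a paint plan to a region
#'
#' Intersects every segment of both tracks with the 0-based half-open
#' window `[start, end)` and drops marker ticks outside it. Clipping to
#' `[0, length)` is the identity; when fill is on, the clipped tracks
#' cover exactly `end - start` bp. A window touching no marker tick
#' still returns the (purely clipped) plan, with a warning.
#'
#' @param paint A [ChromosomePaint-class].
#' @param start,end Window in bp, `0 <= start < end <= length`.
#' @return The clipped [ChromosomePaint-class].
#' @export
setMethod("clipPaint", "ChromosomePaint", function(paint, start, end) {
  stopifnot(start >= 0, start < end, end <= paint@length)
  clip <- function(df) {
    df$start <- pmax(df$start, start)
    df$end <- pmin(df$end, end)
    df <- df[df$start < df$end, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  ticks <- paint@ticks[paint@ticks$pos >= start & paint@ticks$pos <= end, ,
                       drop = FALSE]
  rownames(ticks) <- NULL
  if (nrow(paint@ticks) > 0 && nrow(ticks) == 0)
    warning(sprintf("region [%s, %s) on %s contains no markers",
                    format(start), format(end), paint@chrom), call. = FALSE)
  new("ChromosomePaint", chrom = paint@chrom, length = paint@length,
      track1 = clip(paint@track1), track2 = clip(paint@track2),
      ticks = ticks)
})

#' Advice on marker density versus fill mode
#'
#' With fill on, chromosomes carrying more than 100 markers produce
#' figures dominated by blend transitions; as a rule of thumb fill
#' should then be turned off. Returns the advisory string, or `NULL`
#' when no advice applies. Never an error: the advice is logged by the
#' planning step and rendering proceeds.
#'
#' @param markersPerChrom Marker count on one chromosome.
#' @param fill Logical fill mode.
#' @return A character advisory or `NULL`.
#' @export
#' @examples
#' densityAdvice(101, fill = TRUE)   # advisory
#' densityAdvice(100, fill = TRUE)   # NULL (not exceeding)
densityAdvice <- function(markersPerChrom, fill) {
  stopifnot(markersPerChrom >= 0)
  if (isTRUE(fill) && markersPerChrom > 100)
    sprintf(paste("a chromosome carries %d markers (> 100);",
                  "consider turning fill off for readable figures"),
            markersPerChrom)
  else NULL
}

#' Plan all figures for a table under a configuration
#'
#' Pure planning step: computes every [ChromosomePaint-class] needed
#' and groups them into [FigurePlan-class] objects per the drawing
#' mode, without touching a graphics device.
#'
#' \describe{
#'   \item{normal}{one figure per sample; all chromosomes of the
#'     species in database order, bar lengths proportional to bp.}
#'   \item{compare}{one figure; per chromosome, all samples' copies of
#'     that chromosome aligned side by side.}
#'   \item{zoomed}{one figure showing `config@region` of one
#'     chromosome for all samples, obtained by clipping the
#'     full-chromosome plans.}
#' }
#'
#' Chromosomes present in the species entry but carrying no markers are
#' painted in the `MISSING` role so alignment across samples is kept.
#' Density advisories (see [densityAdvice()]) are emitted as messages.
#'
#' @param x A [GenotypeTable-class].
#' @param db A [ChromLengthDB-class].
#' @param config A [RenderConfig-class]; `config@species` must be in
#'   `db`, and every table chromosome in that species' entry.
#' @param gapRule,lineWidth Passed to [paintTracks()].
#' @return List of [FigurePlan-class] objects.
#' @export
planFigures <- function(x, db, config, gapRule = "blend", lineWidth = NULL) {
  stopifnot(is(x, "GenotypeTable"), is(db, "ChromLengthDB"),
            is(config, "RenderConfig"))
  validObject(config)
  lens <- chromLengths(db, config@species)   # errors listing species
  tabChroms <- unique(x@markers$chrom)
  unknown <- setdiff(tabChroms, names(lens))
  if (length(unknown) > 0)
    stop(sprintf("chromosome(s) %s not present in species '%s'; database has: %s",
                 paste(sQuote(unknown), collapse = ", "), config@species,
                 paste(names(lens), collapse = ", ")), call. = FALSE)

  counts <- table(x@markers$chrom)
  for (ch in names(counts)) {
    adv <- densityAdvice(as.integer(counts[[ch]]), config@fill)
    if (!is.null(adv)) message(ch, ": ", adv)
  }

  paintOne <- function(smp, ch) paintTracks(
    x, smp, ch, lens[[ch]], fill = config@fill,
    coloringMode = config@coloringMode, gapRule = gapRule,
    lineWidth = lineWidth)

  mode <- config@drawingMode
  if (mode == "normal") {
    lapply(x@samples, function(smp) {
      panels <- lapply(names(lens), function(ch)
        list(chrom = ch, length = lens[[ch]],
             paints = stats::setNames(list(paintOne(smp, ch)), smp)))
      new("FigurePlan", mode = mode, title = smp, panels = panels,
          maxLength = max(lens))
    })
  } else if (mode == "compare") {
    panels <- lapply(names(lens), function(ch)
      list(chrom = ch, length = lens[[ch]],
           paints = stats::setNames(lapply(x@samples, paintOne, ch = ch),
                                    x@samples)))
    list(new("FigurePlan", mode = mode, title = "", panels = panels,
             maxLength = max(lens)))
  } else {                                  # zoomed
    r <- config@region
    if (!r$chrom %in% names(lens))
      stop(sprintf("zoom chromosome '%s' not in species '%s'; database has: %s",
                   r$chrom, config@species,
                   paste(names(lens), collapse = ", ")), call. = FALSE)
    if (r$end > lens[[r$chrom]])
      stop("zoom region extends beyond the chromosome length", call. = FALSE)
    paints <- stats::setNames(lapply(x@samples, function(smp)
      clipPaint(paintOne(smp, r$chrom), r$start, r$end)), x@samples)
    panels <- list(list(chrom = r$chrom, length = lens[[r$chrom]],
                        paints = paints))
    list(new("FigurePlan", mode = mode, title = "", panels = panels,
             maxLength = r$end - r$start))
  }
}
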