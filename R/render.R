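## Rendering ---------------------------------------------------------------
##
## The only module that touches a graphics backend. Layout stays pure:
## everything here consumes FigurePlan + ColorSet. Track rectangles are
## rasterized from the paint plan (one color per pixel column) and
## placed with rasterImage(interpolate = FALSE), so fill colors in the
## output are exactly the resolved role colors.

## one row of pixel colors for a track over the bp window xlim
rasterTrackRow <- function(track, xlim, width, colorSet,
                           background = "#FFFFFF") {
  mid <- xlim[1] + (seq_len(width) - 0.5) * (xlim[2] - xlim[1]) / width
  cols <- rep(background, width)
  if (nrow(track) > 0) {
    roleCols <- vapply(track$role, resolveRoleColor, "", colorSet = colorSet)
    for (i in seq_len(nrow(track))) {
      hit <- mid >= track$start[i] & mid < track$end[i]
      cols[hit] <- roleCols[i]
    }
  }
  cols
}

#' Render one haplotype track as a raw pixel strip
#'
#' Writes a PNG in which each pixel column carries the resolved color
#' of the paint segment under it — a direct rasterization of the paint
#' plan with no axes, labels or margins. Useful for pixel-exact
#' verification of a plan and as the primitive behind [render()].
#'
#' @param paint A [ChromosomePaint-class].
#' @param track Track index, 1 or 2.
#' @param colorSet A [ColorSet-class].
#' @param path Output PNG path.
#' @param width,height Pixel dimensions of the strip.
#' @param xlim bp window drawn; defaults to the full chromosome.
#' @return `path`, invisibly.
#' @export
renderTrackStrip <- function(paint, track, colorSet, path,
                             width = 1000, height = 16, xlim = NULL) {
  stopifnot(is(paint, "ChromosomePaint"), track %in% c(1, 2))
  if (is.null(xlim)) xlim <- c(0, paint@length)
  tr <- if (track == 1) paint@track1 else paint@track2
  cols <- rasterTrackRow(tr, xlim, width, colorSet)
  arr <- t(grDevices::col2rgb(cols)) / 255               # width x 3
  img <- array(0, dim = c(height, width, 3))
  for (k in 1:3) img[, , k] <- matrix(rep(arr[, k], each = height),
                                      nrow = height)
  png::writePNG(img, path)
  invisible(path)
}

## draw one full figure on the open device
drawFigure <- function(plan, config, colorSet, rasterWidth = 2000) {
  panels <- plan@panels
  nRows <- sum(vapply(panels, function(p) length(p$paints), 1L))
  rowH <- 1                     # one sample-on-one-chromosome row
  gapH <- 0.6                   # gap between chromosome groups
  totH <- nRows * rowH + length(panels) * gapH
  op <- graphics::par(mar = c(3.5, 7, if (nzchar(plan@title)) 2.5 else 1, 1),
                      xaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, plan@maxLength), ylim = c(0, totH),
                 type = "n", axes = FALSE, xlab = "", ylab = "")
  if (nzchar(plan@title))
    graphics::title(main = plan@title, cex.main = 1.1)

  y <- totH
  for (p in panels) {
    y <- y - gapH
    first <- TRUE
    for (smp in names(p$paints)) {
      paint <- p$paints[[smp]]
      zoomed <- plan@mode == "zoomed"
      xoff <- if (zoomed) config@region$start else 0
      xlim <- if (zoomed) c(config@region$start, config@region$end)
              else c(0, paint@length)
      y0 <- y - rowH
      trackH <- 0.32 * rowH
      for (tk in 1:2) {
        tr <- if (tk == 1) paint@track1 else paint@track2
        cols <- rasterTrackRow(tr, xlim, rasterWidth, colorSet)
        yTop <- y0 + rowH * 0.5 + (if (tk == 1) trackH else 0) + 0.02
        graphics::rasterImage(grDevices::as.raster(matrix(cols, nrow = 1)),
                              xleft = xlim[1] - xoff,
                              ybottom = yTop - trackH,
                              xright = xlim[2] - xoff,
                              ytop = yTop, interpolate = FALSE)
      }
      lab <- if (first) sprintf("%s  %s", p$chrom, smp) else smp
      graphics::mtext(lab, side = 2, at = y0 + rowH * 0.5, las = 1,
                      line = 0.5, cex = 0.7)
      if (config@displayMarkerNames && nrow(paint@ticks) > 0) {
        ticks <- thinTicks(paint@ticks)
        graphics::segments(ticks$pos - xoff, y0 + rowH * 0.42,
                           ticks$pos - xoff, y0 + rowH * 0.5, lwd = 0.5)
        graphics::text(ticks$pos - xoff, y0 + rowH * 0.30, ticks$name,
                       cex = 0.45, srt = 0)
      }
      first <- FALSE
      y <- y0
    }
  }
  axTicks <- pretty(c(0, plan@maxLength))
  graphics::axis(1, at = axTicks, labels = sprintf("%.1f", axTicks / 1e6),
                 cex.axis = 0.7)
  graphics::mtext("position (Mb)", side = 1, line = 2.2, cex = 0.8)
}

## D17: with > 50 labels per chromosome draw every k-th and say so
thinTicks <- function(ticks, maxLabels = 50) {
  n <- nrow(ticks)
  if (n <= maxLabels) return(ticks)
  k <- ceiling(n / maxLabels)
  message(sprintf("%d marker labels; drawing every %d-th to avoid overlap",
                  n, k))
  ticks[seq(1, n, by = k), , drop = FALSE]
}

#' Render a figure plan to PNG (and optionally PDF)
#'
#' Draws a [FigurePlan-class]: each chromosome as two adjacent narrow
#' haplotype tracks whose rectangles take exactly the colors of the
#' plan's segments resolved through the active color set, with marker
#' ticks and names when `config@displayMarkerNames` is on. A PNG at
#' `config@dpi` is always written; a vector PDF is written additionally
#' when `config@pdf` is set.
#'
#' File naming: normal-mode figures are `<stem>_<sample>.<ext>` (the
#' sample is the plan title); compare and zoomed figures are
#' `<stem>.<ext>`.
#'
#' @param plan A [FigurePlan-class] from [planFigures()].
#' @param config A [RenderConfig-class].
#' @param stem Output path stem (no extension).
#' @param colorSets Color-set registry; defaults to the shipped one.
#' @return Character vector of the file(s) written, invisibly.
#' @export
render <- function(plan, config, stem = "genopaint_output",
                   colorSets = loadColorSets()) {
  stopifnot(is(plan, "FigurePlan"), is(config, "RenderConfig"))
  if (length(plan@panels) == 0) stop("empty figure plan", call. = FALSE)
  cs <- getColorSet(colorSets, config@colorSet)
  base <- if (plan@mode == "normal" && nzchar(plan@title))
    paste0(stem, "_", plan@title) else stem

  nRows <- sum(vapply(plan@panels, function(p) length(p$paints), 1L))
  hIn <- max(2, 0.55 * nRows + 0.5 * length(plan@panels) + 1)
  wIn <- 10
  files <- character(0)

  pngFile <- paste0(base, ".png")
  grDevices::png(pngFile, width = wIn, height = hIn, units = "in",
                 res = config@dpi)
  drawFigure(plan, config, cs)
  grDevices::dev.off()
  files <- c(files, pngFile)

  if (config@pdf) {
    pdfFile <- paste0(base, ".pdf")
    grDevices::pdf(pdfFile, width = wIn, height = hIn)
    drawFigure(plan, config, cs)
    grDevices::dev.off()
    files <- c(files, pdfFile)
  }
  invisible(files)
}
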