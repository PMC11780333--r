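test_that("assignRoles depicts phase in 2-color mode and HET in 3-color", {
  het <- Call("B", "A", phased = TRUE)
  expect_identical(unname(assignRoles(het, "2-color")), c("B", "A"))
  expect_identical(unname(assignRoles(het, "3-color")), c("HET", "HET"))
  hom <- Call("A", "A")
  expect_identical(unname(assignRoles(hom, "2-color")), c("A", "A"))
  expect_identical(unname(assignRoles(hom, "3-color")), c("A", "A"))
  miss <- Call("MISSING", "MISSING")
  expect_identical(unname(assignRoles(miss, "2-color")),
                   c("MISSING", "MISSING"))
  ## canonical unphased het: A over B by convention
  expect_identical(unname(assignRoles(Call("A", "B"), "2-color")),
                   c("A", "B"))
})

test_that("blending is the per-channel mean with ties rounded up", {
  expect_identical(blendColors("#FF0000", "#0000FF"), "#800080")
  for (c1 in c("#123456", "#FF00AA")) expect_identical(blendColors(c1, c1), c1)
  expect_identical(blendColors("#102030", "#507090"),
                   blendColors("#507090", "#102030"))
  expect_identical(blendRole("A", "A"), "A")
  expect_identical(blendRole("A", "B"), blendRole("B", "A"))
  cs <- toyColorSet()
  expect_identical(resolveRoleColor(blendRole("A", "B"), cs),
                   blendColors(cs@colors[["A"]], cs@colors[["B"]]))
})

test_that("fill=on paints terminal extensions and blended gaps exactly", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(100L, 300L))
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(c(0L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1), "PHASED"))
  p <- paintTracks(tab, "S1", "c1", 400)
  exp <- data.frame(start = c(0, 100, 300), end = c(100, 300, 400),
                    role = c("A", "blend(A,B)", "B"),
                    stringsAsFactors = FALSE)
  expect_identical(p@track1, exp)
  expect_identical(p@track2, exp)
  expect_identical(sum(p@track1$end - p@track1$start), 400)

  ## one marker extends over the whole chromosome
  one <- normalizeTable(GenotypeTable(
    data.frame(chrom = "c1", name = "m1", pos = 500L),
    "S1", matrix(0L, 1, 1), matrix(0L, 1, 1), "PHASED"))
  p1 <- paintTracks(one, "S1", "c1", 1000)
  expect_identical(p1@track1,
                   data.frame(start = 0, end = 1000, role = "A",
                              stringsAsFactors = FALSE))

  ## equal-genotype neighbors merge into one solid block
  mk3 <- data.frame(chrom = "c1", name = c("a", "b", "c"),
                    pos = c(100L, 200L, 300L))
  same <- normalizeTable(GenotypeTable(
    mk3, "S1", matrix(1L, 3, 1), matrix(1L, 3, 1), "PHASED"))
  ps <- paintTracks(same, "S1", "c1", 400)
  expect_identical(nrow(ps@track1), 1L)
  expect_identical(ps@track1$role, "B")
})

test_that("fill=off draws one centered line per marker", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(100L, 300L))
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(c(0L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1), "PHASED"))
  p <- paintTracks(tab, "S1", "c1", 400, fill = FALSE, lineWidth = 10)
  expect_identical(nrow(p@track1), 2L)
  expect_identical(p@track1$start, c(95, 295))
  expect_identical(p@track1$end, c(105, 305))
  expect_identical(p@track1$role, c("A", "B"))
  ## default width scales with chromosome length, floor 1 bp
  expect_identical(defaultLineWidth(400), 1)
  expect_identical(defaultLineWidth(2e6), 2000)
})

test_that("marker positions beyond the chromosome length are an error", {
  mk <- data.frame(chrom = "c1", name = "far", pos = 900L)
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(0L, 1, 1), matrix(0L, 1, 1), "PHASED"))
  expect_error(paintTracks(tab, "S1", "c1", 500), "far")
})

test_that("a zero-marker chromosome is painted missing, with a notice", {
  tab <- toyTable()
  expect_message(p <- paintTracks(tab, "S1", "c9", 800), "no markers")
  expect_identical(p@track1$role, "MISSING")
  expect_identical(p@track1$end - p@track1$start, 800)
  expect_identical(nrow(p@ticks), 0L)
})

test_that("clipPaint intersects segments and keeps coverage", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(100L, 300L))
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(c(0L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1), "PHASED"))
  p <- paintTracks(tab, "S1", "c1", 400)
  expect_identical(clipPaint(p, 0, 400)@track1, p@track1)   # identity clip
  cl <- clipPaint(p, 150, 350)
  expect_identical(cl@track1,
                   data.frame(start = c(150, 300), end = c(300, 350),
                              role = c("blend(A,B)", "B"),
                              stringsAsFactors = FALSE))
  expect_identical(sum(cl@track1$end - cl@track1$start), 350 - 150)
  ## a window between the two markers: pure blend, plus a warning
  expect_warning(mid <- clipPaint(p, 150, 250), "no markers")
  expect_identical(mid@track1$role, "blend(A,B)")
  expect_error(clipPaint(p, 300, 200))
})

test_that("the density advisory triggers strictly above 100 markers under fill", {
  expect_null(densityAdvice(100, fill = TRUE))
  expect_match(densityAdvice(101, fill = TRUE), "101")
  expect_null(densityAdvice(10000, fill = FALSE))
  expect_null(densityAdvice(0, fill = TRUE))
})

test_that("planFigures produces one plan per sample (normal) or one figure", {
  tab <- simulateTable(simulationParams(nSamples = 3, seed = 11,
                                        missingRate = 0))
  db <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                   c(chr1 = 1e6, chr2 = 8e5))
  plans <- planFigures(tab, db, renderConfig(species = "toy"))
  expect_length(plans, 3L)
  expect_identical(vapply(plans, function(p) p@title, ""),
                   c("S1", "S2", "S3"))
  expect_length(plans[[1]]@panels, 2L)       # chromosomes in DB order

  cmp <- planFigures(tab, db, renderConfig(species = "toy",
                                           drawingMode = "compare"))
  expect_length(cmp, 1L)
  expect_length(cmp[[1]]@panels, 2L)
  for (panel in cmp[[1]]@panels)
    expect_identical(names(panel$paints), c("S1", "S2", "S3"))

  ## unknown species / chromosome errors list what is available
  expect_error(planFigures(tab, db, renderConfig(species = "unicorn")),
               "toy")
  db2 <- addSpecies(db, "partial", c(chr1 = 1e6))
  expect_error(planFigures(tab, db2, renderConfig(species = "partial")),
               "chr2")

  ## zoomed without a region is rejected at config level
  expect_error(renderConfig(drawingMode = "zoomed", species = "toy"),
               "region")
  expect_error(renderConfig(drawingMode = "zoomed", species = "toy",
                            region = list(chrom = "chr1", start = 5e5,
                                          end = 5e5)),
               "start < end")
})

test_that("paint partition invariant holds over randomized tables", {
  nTables <- 0
  for (seed in 1:100) {
    for (d in c("PHASED", "SIMPLE")) {
      tab <- randomTable(seed, dialect = d)
      nTables <- nTables + 1
      for (smp in sampleNames(tab)) {
        p <- paintTracks(tab, smp, "c1", 1200,
                         coloringMode = sample(c("2-color", "3-color"), 1))
        for (tr in list(p@track1, p@track2)) {
          expect_true(all(diff(tr$start) > 0))            # sorted
          expect_true(all(tr$end > tr$start))
          expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))  # contiguous
          expect_identical(sum(tr$end - tr$start), 1200)  # exact coverage
        }
      }
    }
  }
  expect_gte(nTables, 200)
})

test_that("3-color plans are invariant under phased het flips", {
  for (seed in 1:20) {
    tab <- randomTable(seed, dialect = "PHASED")
    flipped <- GenotypeTable(markers(tab), sampleNames(tab),
                             hapMatrix(tab, 2), hapMatrix(tab, 1),
                             "PHASED")
    for (smp in sampleNames(tab))
      expect_identical(
        paintTracks(flipped, smp, "c1", 1200, coloringMode = "3-color"),
        paintTracks(tab, smp, "c1", 1200, coloringMode = "3-color"))
  }
})

test_that("2-color plans swap tracks exactly when haplotypes are swapped", {
  for (seed in 1:20) {
    tab <- randomTable(seed, dialect = "PHASED")
    swapped <- GenotypeTable(markers(tab), sampleNames(tab),
                             hapMatrix(tab, 2), hapMatrix(tab, 1),
                             "PHASED")
    for (smp in sampleNames(tab)) {
      a <- paintTracks(tab, smp, "c1", 1200, coloringMode = "2-color")
      b <- paintTracks(swapped, smp, "c1", 1200, coloringMode = "2-color")
      expect_identical(b@track1, a@track2)
      expect_identical(b@track2, a@track1)
    }
  }
})

test_that("the zoomed-mode plan equals clipping the full-chromosome plan", {
  tab <- simulateTable(simulationParams(nSamples = 2, seed = 5))
  db <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                   c(chr1 = 1e6, chr2 = 8e5))
  cfg <- renderConfig(species = "toy", drawingMode = "zoomed",
                      region = list(chrom = "chr1", start = 2e5, end = 7e5))
  zoom <- planFigures(tab, db, cfg)[[1]]
  for (smp in sampleNames(tab)) {
    full <- paintTracks(tab, smp, "chr1", 1e6)
    expect_identical(zoom@panels[[1]]$paints[[smp]]@track1,
                     clipPaint(full, 2e5, 7e5)@track1)
    expect_identical(zoom@panels[[1]]$paints[[smp]]@track2,
                     clipPaint(full, 2e5, 7e5)@track2)
  }
})

test_that("layout is deterministic and matches the per-bp oracle on small tables", {
  for (seed in 1:25) {
    tab <- randomTable(seed, nChrom = 1, nMarkers = sample(1:5, 1),
                       nSamples = 1, dialect = "PHASED")
    len <- 1100
    for (mode in c("2-color", "3-color")) {
      p <- paintTracks(tab, "S1", "c1", len, coloringMode = mode)
      expect_identical(p, paintTracks(tab, "S1", "c1", len,
                                      coloringMode = mode))
      pos <- markers(tab)$pos
      for (tk in 1:2) {
        roles <- rolesFor(tab, "S1", "c1", mode, tk)
        oracle <- bpOracle(roles, pos, len)
        got <- expandTrack(if (tk == 1) p@track1 else p@track2, len)
        expect_identical(got, oracle)
      }
    }
  }
})

test_that("the midpoint gap rule is available and also partitions exactly", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(100L, 300L))
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(c(0L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1), "PHASED"))
  p <- paintTracks(tab, "S1", "c1", 400, gapRule = "midpoint")
  expect_identical(p@track1,
                   data.frame(start = c(0, 200), end = c(200, 400),
                              role = c("A", "B"), stringsAsFactors = FALSE))
})
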