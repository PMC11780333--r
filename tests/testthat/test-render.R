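test_that("strip pixels at segment centers carry the resolved plan colors", {
  mk <- data.frame(chrom = "c1", name = c("m1", "m2"), pos = c(100L, 300L))
  tab <- normalizeTable(GenotypeTable(
    mk, "S1", matrix(c(0L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1), "PHASED"))
  p <- paintTracks(tab, "S1", "c1", 400)
  cs <- toyColorSet()
  got <- probeStrip(p, 1, cs)
  expect_identical(got, vapply(p@track1$role, resolveRoleColor, "",
                               colorSet = cs, USE.NAMES = FALSE))
  ## the middle segment really is the blend of the two flanking colors
  expect_identical(got[2], blendColors(cs@colors[["A"]], cs@colors[["B"]]))
})

test_that("pixel fidelity holds for randomized paints and both tracks", {
  cs <- getColorSet(loadColorSets(), "Aqua")
  for (seed in 1:5) {
    tab <- randomTable(seed, nChrom = 1, nMarkers = 4, nSamples = 1)
    p <- paintTracks(tab, "S1", "c1", 1200, coloringMode = "3-color")
    for (tk in 1:2) {
      tr <- if (tk == 1) p@track1 else p@track2
      expect_identical(probeStrip(p, tk, cs, width = 6000),
                       vapply(tr$role, resolveRoleColor, "",
                              colorSet = cs, USE.NAMES = FALSE))
    }
  }
})

test_that("render writes one PNG per sample in normal mode, PDF additively", {
  tab <- simulateTable(simulationParams(nSamples = 3, seed = 3))
  db <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                   c(chr1 = 1e6, chr2 = 8e5))
  cfg <- renderConfig(species = "toy", dpi = 60)
  plans <- planFigures(tab, db, cfg)
  old <- setwd(tempdir()); on.exit(setwd(old))
  for (pl in plans) render(pl, cfg, stem = "out")
  expect_true(all(file.exists(c("out_S1.png", "out_S2.png", "out_S3.png"))))

  cfg2 <- renderConfig(species = "toy", drawingMode = "compare",
                       dpi = 60, pdf = TRUE)
  files <- render(planFigures(tab, db, cfg2)[[1]], cfg2, stem = "cmp")
  expect_setequal(basename(files), c("cmp.png", "cmp.pdf"))
  expect_true(all(file.exists(files)))
  expect_gt(file.size("cmp.pdf"), 0)
})

test_that("render rejects empty plans and unknown color sets", {
  empty <- new("FigurePlan", mode = "normal", title = "S1",
               panels = list(), maxLength = 1)
  cfg <- renderConfig(species = "toy")
  expect_error(render(empty, cfg, stem = tempfile()), "empty")

  tab <- simulateTable(simulationParams(nSamples = 1, seed = 2))
  db <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                   c(chr1 = 1e6, chr2 = 8e5))
  badCfg <- renderConfig(species = "toy", colorSet = "unicorn", dpi = 60)
  plan <- planFigures(tab, db, badCfg)[[1]]
  expect_error(render(plan, badCfg, stem = tempfile()), "available")
})

test_that("dense marker labels are thinned with a notice", {
  tab <- simulateTable(simulationParams(nSamples = 1, seed = 4,
                                        markersPerChrom = 80,
                                        chromLengths = c(chr1 = 1e6),
                                        missingRate = 0))
  db <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                   c(chr1 = 1e6))
  cfg <- renderConfig(species = "toy", dpi = 60, fill = FALSE)
  plan <- planFigures(tab, db, cfg)[[1]]
  old <- setwd(tempdir()); on.exit(setwd(old))
  expect_message(render(plan, cfg, stem = "dense"), "every")
})
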