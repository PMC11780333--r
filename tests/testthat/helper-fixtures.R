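## Fixture builders and independent oracles, all generated in code.

## small deterministic table: 2 chromosomes, hand-written calls
toyTable <- function(dialect = "PHASED") {
  mk <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                   name = c("m1", "m2", "m3", "m4"),
                   pos = c(100L, 300L, 700L, 250L),
                   stringsAsFactors = FALSE)
  ## S1: AA, het(B|A), BB, missing ; S2: BB, AA, het(A|B), AA
  h1 <- matrix(c(0L, 1L, 1L, NA, 1L, 0L, 0L, 0L), ncol = 2)
  h2 <- matrix(c(0L, 0L, 1L, NA, 1L, 0L, 1L, 0L), ncol = 2)
  if (dialect != "PHASED") {    # canonicalize hets for unphased dialects
    swap <- !is.na(h1) & h1 > h2
    tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
  }
  normalizeTable(GenotypeTable(mk, c("S1", "S2"), h1, h2, dialect))
}

## random table straight from random allele codes (wider case coverage
## than the simulator: duplicate positions, missingness, both dialects)
randomTable <- function(seed, nChrom = 2, nMarkers = 8, nSamples = 2,
                        dialect = "PHASED", missingRate = 0.15) {
  set.seed(seed)
  mk <- do.call(rbind, lapply(seq_len(nChrom), function(ci) {
    pos <- sort(sample.int(1000, nMarkers, replace = TRUE))
    data.frame(chrom = paste0("c", ci),
               name = sprintf("c%d_m%d", ci, seq_len(nMarkers)),
               pos = pos, stringsAsFactors = FALSE)
  }))
  n <- nrow(mk) * nSamples
  h1 <- matrix(sample(0:1, n, replace = TRUE), nrow(mk))
  h2 <- matrix(sample(0:1, n, replace = TRUE), nrow(mk))
  miss <- matrix(runif(n) < missingRate, nrow(mk))
  h1[miss] <- NA_integer_; h2[miss] <- NA_integer_
  if (dialect != "PHASED") {
    swap <- !is.na(h1) & h1 > h2
    tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
  }
  normalizeTable(GenotypeTable(mk, sprintf("S%d", seq_len(nSamples)),
                               h1, h2, dialect))
}

writeTempText <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## minimal VCF text from per-record GT token rows
vcfText <- function(records, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(records, function(r)
      paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".", ".", "GT",
              r$gt), collapse = "\t"), ""))
}

vcfRec <- function(chrom = "Chr01", pos = 100, id = ".", ref = "A",
                   alt = "T", gt = c("0|1", "1|1")) {
  list(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt, gt = gt)
}

## brute-force per-bp role oracle for fill=on (evaluates the gap rule
## pointwise, independently of the segment construction)
bpOracle <- function(roles, pos, len) {
  out <- character(len)
  for (bp in 0:(len - 1)) {
    if (bp < pos[1]) { out[bp + 1] <- roles[1]; next }
    if (bp >= pos[length(pos)]) { out[bp + 1] <- roles[length(roles)]; next }
    i <- max(which(pos <= bp))
    j <- min(which(pos > bp))
    out[bp + 1] <- blendRole(roles[i], roles[j])
  }
  out
}

## expand a segment track to one role per bp
expandTrack <- function(track, len) {
  out <- rep(NA_character_, len)
  for (i in seq_len(nrow(track)))
    out[(track$start[i] + 1):track$end[i]] <- track$role[i]
  out
}

## character-count FASTA oracle (independent of Biostrings)
fastaOracle <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  lens <- tapply(nchar(gsub("\\s", "", lines[!hdr])), grp[!hdr], sum)
  stats::setNames(as.numeric(lens), ids)
}

## roles of one sample's calls on one chromosome, by the exported scalar API
rolesFor <- function(tab, sample, chrom, mode, track) {
  idx <- which(markers(tab)$chrom == chrom)
  vapply(idx, function(i)
    assignRoles(callAt(tab, i, sample), mode)[[track]], "")
}

toyColorSet <- function() getColorSet(loadColorSets(), "normal")

## probe the pixel at each segment's center in a rendered strip
probeStrip <- function(paint, track, colorSet, width = 2000) {
  path <- tempfile(fileext = ".png")
  renderTrackStrip(paint, track, colorSet, path, width = width, height = 4)
  img <- png::readPNG(path)
  tr <- if (track == 1) paint@track1 else paint@track2
  vapply(seq_len(nrow(tr)), function(i) {
    mid <- (tr$start[i] + tr$end[i]) / 2
    px <- min(width, max(1, ceiling(mid / paint@length * width)))
    grDevices::rgb(img[2, px, 1], img[2, px, 2], img[2, px, 3])
  }, "")
}
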