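## Synthetic genotype data -------------------------------------------------
##
## Deterministic simulator of biparental-population genotype tables:
## each haplotype is a mosaic of parent-A and parent-B blocks separated
## by a Poisson number of crossover breakpoints at uniform positions.
## It exists so every other module is testable without downloads, and
## its defaults describe a small clean mapping population.

#' Simulation parameters
#'
#' @param nSamples Number of samples.
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param markersPerChrom Markers per chromosome (>= 1).
#' @param crossoverRate Expected crossovers per chromosome per gamete
#'   (Poisson mean); 2 approximates a typical plant chromosome of a
#'   couple of Morgans.
#' @param hetFraction Probability, per sample and chromosome, that the
#'   second haplotype is simulated independently of the first (allowing
#'   heterozygosity) instead of copying it (fully inbred).
#' @param missingRate Per-call probability of a missing genotype.
#' @param dialect Output encoding dialect (see [listDialects()]).
#' @param seed Integer seed fixing all randomness.
#' @param markerPlacement `"even"` (default, a regular grid as in clean
#'   mapping data) or `"random"` (uniform positions).
#' @return Validated parameter list for [simulateTable()].
#' @export
simulationParams <- function(nSamples = 3,
                             chromLengths = c(chr1 = 1e6, chr2 = 8e5),
                             markersPerChrom = 20, crossoverRate = 2,
                             hetFraction = 0.5, missingRate = 0.02,
                             dialect = "PHASED", seed = 1,
                             markerPlacement = c("even", "random")) {
  stopifnot(nSamples >= 1, length(chromLengths) >= 1,
            !is.null(names(chromLengths)), all(chromLengths >= 1),
            crossoverRate >= 0, hetFraction >= 0, hetFraction <= 1,
            missingRate >= 0, missingRate <= 1)
  if (markersPerChrom < 1) stop("markersPerChrom must be >= 1", call. = FALSE)
  list(nSamples = nSamples, chromLengths = chromLengths,
       markersPerChrom = markersPerChrom, crossoverRate = crossoverRate,
       hetFraction = hetFraction, missingRate = missingRate,
       dialect = match.arg(dialect, listDialects()), seed = as.integer(seed),
       markerPlacement = match.arg(markerPlacement))
}

## one haplotype: breakpoints + allele lookup. Alleles alternate between
## blocks; the leftmost block allele is a fair coin.
simHap <- function(len, rate) {
  k <- stats::rpois(1, rate)
  breaks <- sort(stats::runif(k, min = 0, max = len))
  start <- stats::rbinom(1, 1, 0.5)
  list(breaks = breaks, start = start)
}

hapAllele <- function(hap, pos) {
  (hap$start + findInterval(pos, hap$breaks)) %% 2L
}

#' Simulate recombinant haplotypes
#'
#' Draws `n` haplotypes over a chromosome of length `len`: each has
#' `Poisson(rate)` crossover breakpoints at uniform positions,
#' alternating parent-A/parent-B blocks. Used by [simulateTable()];
#' exposed so the breakpoint process itself can be checked (the mean
#' breakpoint count recovers the Poisson mean).
#'
#' @param n Number of haplotypes.
#' @param len Chromosome length in bp.
#' @param rate Poisson mean of crossovers per haplotype.
#' @param seed Integer seed.
#' @return List of haplotypes; each a `list(breaks = <sorted bp
#'   positions>, start = <0 or 1>)`.
#' @export
simulateHaplotypes <- function(n, len, rate, seed = 1) {
  set.seed(seed)
  replicate(n, simHap(len, rate), simplify = FALSE)
}

#' Simulate a genotype table
#'
#' Generates a fully reproducible [GenotypeTable-class]: per sample and
#' chromosome, two recombinant haplotypes (see [simulateHaplotypes()];
#' the second is independent with probability `hetFraction`, else a
#' copy of the first), read off at the marker grid, with missing calls
#' injected at `missingRate`. The returned table passes
#' [normalizeTable()] validation by construction; its metadata records
#' the number of breakpoints of every simulated haplotype.
#'
#' @param params From [simulationParams()].
#' @return A normalized [GenotypeTable-class] in `params$dialect`.
#' @export
#' @examples
#' tab <- simulateTable(simulationParams(nSamples = 2, seed = 42))
#' tab
simulateTable <- function(params = simulationParams()) {
  set.seed(params$seed)
  chroms <- names(params$chromLengths)
  m <- params$markersPerChrom
  markerList <- list(); h1 <- list(); h2 <- list()
  samples <- sprintf("S%d", seq_len(params$nSamples))
  breakCounts <- integer(0)

  for (ch in chroms) {
    len <- params$chromLengths[[ch]]
    pos <- if (params$markerPlacement == "even") {
      unique(pmax(1, floor(seq_len(m) * len / (m + 1))))
    } else {
      sort(unique(ceiling(stats::runif(m, 0, len))))
    }
    markerList[[ch]] <- data.frame(
      chrom = ch, name = sprintf("%s_%d", ch, pos), pos = as.integer(pos),
      stringsAsFactors = FALSE)
    a1 <- matrix(NA_integer_, length(pos), params$nSamples)
    a2 <- matrix(NA_integer_, length(pos), params$nSamples)
    for (s in seq_len(params$nSamples)) {
      hapA <- simHap(len, params$crossoverRate)
      het <- stats::runif(1) < params$hetFraction
      hapB <- if (het) simHap(len, params$crossoverRate) else hapA
      breakCounts <- c(breakCounts, length(hapA$breaks),
                       if (het) length(hapB$breaks))
      a1[, s] <- hapAllele(hapA, pos)
      a2[, s] <- hapAllele(hapB, pos)
      miss <- stats::runif(length(pos)) < params$missingRate
      a1[miss, s] <- NA_integer_; a2[miss, s] <- NA_integer_
    }
    h1[[ch]] <- a1; h2[[ch]] <- a2
  }

  hap1 <- do.call(rbind, h1); hap2 <- do.call(rbind, h2)
  if (params$dialect != "PHASED") {
    swap <- !is.na(hap1) & hap1 > hap2      # canonicalize het order
    tmp <- hap1[swap]; hap1[swap] <- hap2[swap]; hap2[swap] <- tmp
  }
  tab <- GenotypeTable(do.call(rbind, markerList), samples, hap1, hap2,
                       params$dialect,
                       metadata = list(simulation = params,
                                       breakpointCounts = breakCounts))
  normalizeTable(tab)
}

#' Write a genotype table as a synthetic VCF
#'
#' Emits a minimal valid VCF v4.2 (fileformat line, contig lines,
#' GT-only FORMAT) from a PHASED or UNPHASED table, with REF `A` and
#' ALT `T` placeholder alleles and marker names in the ID column.
#' [convertVcf()] on the output round-trips to an equivalent table.
#' SIMPLE tables have no VCF encoding and are rejected.
#'
#' @param x A [GenotypeTable-class], dialect PHASED or UNPHASED.
#' @param path Output VCF path.
#' @param contigLengths Optional named lengths for the `##contig`
#'   header lines; defaults to each chromosome's last marker position.
#' @return `path`, invisibly.
#' @export
writeSyntheticVcf <- function(x, path, contigLengths = NULL) {
  stopifnot(is(x, "GenotypeTable"))
  if (x@dialect == "SIMPLE")
    stop("SIMPLE tables have no VCF encoding; use a PHASED or UNPHASED table",
         call. = FALSE)
  m <- x@markers
  if (is.null(contigLengths))
    contigLengths <- tapply(m$pos, factor(m$chrom, unique(m$chrom)), max)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                   as.integer(contigLengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x@samples), collapse = "\t"))
  tok <- matrix(serializeCodes(as.vector(x@hap1), as.vector(x@hap2),
                               x@dialect), nrow = nrow(m))
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(m$chrom[i], m$pos[i], m$name[i], "A", "T", ".", ".", ".", "GT",
            tok[i, ]), collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
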