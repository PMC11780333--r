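---
title: "Painting graphical genotypes: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting graphical genotypes: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genopaint)
```

## The problem

A *graphical genotype* depicts, along each chromosome, which
parental or ancestral allele every genotyped marker carries, as
colored blocks. In breeding populations and comparative genomics this
turns a variant matrix of thousands of calls into a picture in which
recombination breakpoints, heterozygous stretches and introgression
blocks — contiguous runs of a donor's color — can be read at a glance.

genopaint takes a markers × samples table of diploid calls and draws
each chromosome as **two narrow haplotype tracks**, one per haplotype.
With phased input the two tracks are the two phased haplotypes, so
phase switches are directly visible; with unphased or simple input the
tracks carry a fixed documented convention (below).

## The data model

Calls are ordered pairs of allele states over exactly three states:
`A` (reference / parent 1), `B` (alternate / parent 2) and `MISSING`.
If either haplotype of a call is missing, both are: none of the three
missing tokens carries partial information. Three encoding dialects
exist, one per table, never mixed:

| dialect  | calls                      | missing | phased |
|----------|----------------------------|---------|--------|
| SIMPLE   | `A`, `B`, `H`              | `N`     | never  |
| PHASED   | `0|0`, `1|1`, `1|0`, `0|1` | `.|.`   | always |
| UNPHASED | `0/0`, `1/1`, `1/0`, `0/1` | `./.`   | never  |

Polyploid calls (three or more allele fields, e.g. `0/0/0/1`) and
multi-allelic calls (any allele index ≥ 2, e.g. `0/2`) are rejected as
unsupported rather than silently coerced. Since an unphased
heterozygote's order carries no information, `1/0` is canonicalized to
`0/1` on parsing; this is the only way in which a round trip through
`writeGenotypeCsv()` is not the bit-exact identity.

Marker positions are 1-based bp (the VCF convention). Internally,
paint segments use 0-based half-open intervals `[start, end)` so that
a track's segment lengths sum *exactly* to the chromosome length — the
partition invariant the test suite checks on randomized tables.

### The leading CSV columns

Genotype CSVs in the wild carry either three leading metadata columns
(chromosome, marker name, physical position) or four (with a genetic
position, in cM, between name and physical position). The reader
auto-detects the layout from header names (a genetic-sounding third
header such as `cM` followed by a position-like fourth) and accepts an
explicit `metaCols` override; the genetic position is carried in the
marker table but never used for layout, which is strictly physical.
This tolerance is deliberate: the four-column variant is common in
linkage-map exports, and guessing wrong is loud (the position column
fails integer validation) rather than silent.

## From calls to colors

Each call maps to a pair of *color roles*, one per track:

* homozygotes and missing calls put the same role on both tracks
  (`A`/`A`, `B`/`B`, `MISSING`/`MISSING`);
* in **3-color** mode a heterozygote puts the dedicated `HET` role on
  both tracks;
* in **2-color** mode each track shows its own haplotype, so a phased
  `1|0` is drawn `B` over `A` — this is where phasing becomes visible.
  The canonical unphased heterozygote is drawn `A` over `B`; since
  unphased order is arbitrary, this is a convention, stated here and
  in `?assignRoles`, not information.

Roles resolve to colors through a named color set (four roles: `A`,
`B`, `het`, `missing`), loaded from a user-editable JSON registry that
ships with at least `normal` and `Aqua`.

### Fill semantics

With `fill = TRUE` the whole chromosome is painted:

* `[0, p1)` and `[pn, length)` extend the terminal markers' roles
  (published graphical genotypes show fully colored chromosomes);
* each inter-marker gap `[pi, pi+1)` is painted **one uniform blend**
  of the two flanking markers' colors — the per-channel arithmetic
  mean, ties rounded up, so `#FF0000` + `#0000FF` gives `#800080`.
  When the two flanking roles agree the gap simply takes that role,
  and runs of equal genotype coalesce into solid blocks.

Whether gaps should be blended uniformly or split at the midpoint is a
genuinely open design point; the uniform blend matches the intent that
the gap "reflects the colors of the two adjacent markers", and the
alternative is implemented behind `gapRule = "midpoint"` so the choice
is one argument, not a fork. The blend rule is evaluated pointwise by
an independent per-bp oracle in the tests, which must agree with the
segment construction base pair by base pair.

With `fill = FALSE` only the markers themselves are drawn, as lines of
width `max(1, round(length/1000))` bp — one-bp lines vanish at genome
scale, and 1/1000 of the chromosome keeps them visible at any zoom;
the width is a parameter (`lineWidth`) for callers who disagree. As a
rule of thumb, fill should be off above 100 markers per chromosome;
`densityAdvice()` emits exactly that advisory (strictly above 100,
fill on only), as a notice, never an error.

### Degenerate inputs

* A chromosome present in the species entry but carrying no markers is
  painted full-length in the `MISSING` role (with a notice) rather
  than omitted, so compare-mode panels stay aligned across samples.
* Markers whose position exceeds the database chromosome length are an
  error naming the marker — this almost always means the wrong species
  or assembly was selected.
* Duplicate (chromosome, position) pairs are retained in input order;
  their zero-width gap simply drops out of the paint.
* Clipping a plan to a window containing no marker is legal (the gap
  blend still defines a color) and warns.

## Drawing modes and rendering

`planFigures()` is pure: *normal* mode yields one figure plan per
sample (all chromosomes in database insertion order — insertion order,
not lexicographic, so `chr2` precedes `chr10`); *compare* yields one
plan with every sample's copy of each chromosome aligned; *zoomed*
yields one plan over a `--chr/--start/--end` window, defined by
construction as `clipPaint()` of the full-chromosome plan — the test
suite still checks the two code paths agree.

Only `render()` touches a graphics device. Track rectangles are
rasterized straight from the paint plan — one resolved color per pixel
column — and placed with `rasterImage(interpolate = FALSE)`, so fill
colors in the output are exactly the plan's colors; `renderTrackStrip()`
exposes that rasterization directly, and the tests probe the pixel at
every segment's center and require exact equality with the resolved
role color. PNG is always produced at `dpi` (default 300, a
print-quality default); PDF is additive. Marker-name labels thin to at
most 50 per chromosome (every k-th, with a notice) because horizontal
labels overlap beyond that.

## The synthetic-data generator

`simulateTable()` emulates a small biparental mapping population, the
setting graphical genotypes were designed for: per sample and
chromosome, haplotypes are alternating parent-A/parent-B mosaics with
`Poisson(crossoverRate)` breakpoints at uniform positions
(`crossoverRate = 2` by default — a chromosome of roughly two
Morgans), read off at an evenly spaced marker grid (clean mapping
panels; `markerPlacement = "random"` is available), with missing calls
injected at `missingRate = 0.02`, a typical post-filtering rate. The
`hetFraction` parameter (default 0.5) is the probability that the
second haplotype is simulated independently of the first — else it is
a copy — so it interpolates between a fully inbred panel (0) and an
F1-like heterozygous one (1); this operational definition is this
package's own.

The generator is deliberately simpler than real data: no genotyping
error (missingness is the only noise), no segregation distortion, no
linkage-map (cM) geometry, uniform breakpoint placement with no
interference, and biallelic diploid records only. Passing tests
therefore demonstrate the *bookkeeping* — parsing, layout geometry,
round trips, rendering fidelity — not robustness to messy real-world
VCFs, which should be filtered upstream (the package intentionally
ignores QUAL/FILTER/INFO and rejects rather than repairs mixed
phasing).

Default problem sizes in the tests and the acceptance script — 2–3
samples, two chromosomes of 0.8–1 Mb, 20 markers per chromosome, 500
haplotypes for the Poisson-recovery check — were chosen as the
smallest sizes at which every geometric and statistical property under
test is non-trivial (multiple blocks per chromosome, ≥ 3 standard
errors of resolution on the crossover rate).

## The shipped chromosome-length database

Eight species ship in `chromosome_length_database.json` (rice,
sorghum, maize, bread wheat, barley, soybean, tomato, arabidopsis);
the values are approximate figures recorded once from public reference
assemblies and exist to scale figures, not to serve as an
assembly-exact resource — tests pin the species count and per-species
chromosome counts, not exact bp, precisely because assembly versions
drift. New species are added from a genome FASTA
(`scanFastaLengths()` + `addSpecies()`, or the `genopaint-add-species`
script); record order in the FASTA defines drawing order.

## Known limitations

* Physical coordinates only; no genetic-map (cM) scaling.
* Diploid, biallelic calls only; one dialect per table.
* No per-marker quality shading or recombination-count annotation.
* The figure geometry (margins, track heights) is a set of sensible
  fixed defaults, not a styling API.
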