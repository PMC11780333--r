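# genopaint

Graphical genotypes from variant calling data.

A graphical genotype shows, along each chromosome, which parental or
ancestral allele every marker carries, as colored blocks — the
standard way to see recombination breakpoints, heterozygous stretches
and introgression blocks in breeding populations, genetic mapping and
comparative genomics. genopaint turns a markers × samples table of
diploid calls (CSV, or a VCF converted to it) into chromosome-scale
paintings in which **each chromosome is two narrow haplotype tracks**
of colored segments, exported as PNG and/or PDF.

For whom: plant/animal breeders and geneticists with variant calling
data who want publication-quality, customizable chromosome paintings —
including *phased* data, where the two tracks are the two phased
haplotypes and phase switches are directly visible.

## The model in brief

A call is an ordered pair of allele states over {A, B, MISSING} plus a
phased flag, written in one of three dialects: simple `A/B/H/N`,
phased `0|0, 0|1, 1|0, 1|1, .|.`, or unphased `0/0, 0/1, 1/0, 1/1,
./.` (one dialect per table; polyploid calls like `0/0/0/1` and
multi-allelic calls like `0/2` are rejected). Each call maps to a
color role per track — in 2-color mode a phased `1|0` paints B over A;
in 3-color mode heterozygotes get a third color. With fill on, the gap
between markers *i* and *i+1* over `[p_i, p_{i+1})` is painted the
per-channel mean of the flanking colors (ties round up), terminal
segments extend the end markers, and each track's segments partition
`[0, L)` exactly, with L the chromosome length from a species
database. Three drawing modes: `normal` (genome-wide, one figure per
sample), `compare` (all samples aligned per chromosome), `zoomed` (a
`chr:start-end` window, defined as clipping the full plan).

## Worked example

```r
library(genopaint)

## a small simulated biparental population: 3 samples, 2 chromosomes
tab <- simulateTable(simulationParams(nSamples = 3, seed = 42))
tab
#> GenotypeTable: 40 markers x 3 samples [PHASED dialect]
#>   chromosomes (2): chr1(20) chr2(20)
#>   samples: S1, S2, S3

## the paint plan of sample S1 on chr1 (two tracks of segments)
p <- paintTracks(tab, "S1", "chr1", 1e6)
p
#> ChromosomePaint chr1 (1,000,000 bp): 9 + 9 segments, 20 ticks
head(p@track1, 5)
#>    start    end       role
#> 1      0 285714          B
#> 2 285714 333333 blend(A,B)
#> 3 333333 619047          A
#> 4 619047 666666 blend(A,B)
#> 5 666666 809523          B
```

Reading: S1's first haplotype is parent-B up to the marker at 285,714
bp, crosses over to parent-A by 333,333 bp (the gap between the two
markers is blended), back to B around 666 kb — two crossovers visible
as three blocks. `sum(end - start)` is exactly 1,000,000: the track
partitions the chromosome.

```r
## draw: one PNG per sample, chromosomes scaled by bp
db  <- addSpecies(new("ChromLengthDB", entries = list()), "toy",
                  c(chr1 = 1e6, chr2 = 8e5))
cfg <- renderConfig(species = "toy")
for (plan in planFigures(tab, db, cfg))
  render(plan, cfg, stem = "example")
#> writes example_S1.png, example_S2.png, example_S3.png
```

Real species skip the `addSpecies()` step: a database with eight crop
and model species ships with the package (`loadChromLengthDB()`;
rice, sorghum, maize, wheat, barley, soybean, tomato, arabidopsis),
and new species are added from a genome FASTA.

## Command line

Thin Rscript wrappers under `exec/` expose the same pipeline:

```sh
genopaint-convert input.vcf genotypes.csv --add_marker_names
genopaint-draw -i genotypes.csv -s rice --drawing_mode compare --coloring_mode 3-color
genopaint-add-species --fasta genome.fa --database chrdb.json --name my_species
```

`genopaint-draw --help` lists the full flag surface (`--fill`,
`--color_set`, `--display_marker_names`, `--chr/--start/--end`,
`--dpi`, `--pdf`, ...); boolean flags take `on`/`off` values. The VCF
converter keeps biallelic diploid records only and prints an exact
accounting (`total = kept + dropped_multiallelic + dropped_nondiploid
+ dropped_other`).

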