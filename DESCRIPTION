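Package: genopaint
Title: Graphical Genotypes from Variant Calling Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts marker genotype tables (CSV) and standard VCF files
    into graphical genotypes: chromosome-scale paintings in which every
    chromosome is drawn as two haplotype tracks of colored genomic
    segments. Supports three genotype encoding dialects (simple A/B/H/N,
    phased 0|1, unphased 0/1), genome-wide, cross-sample comparison and
    zoomed region views, two coloring modes, optional inter-marker fill
    with color blending, a chromosome-length database for eight crop and
    model species extensible from genome FASTA files, user-editable color
    sets, PNG/PDF export, and a deterministic simulator of biparental
    genotype tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    vcfR,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
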