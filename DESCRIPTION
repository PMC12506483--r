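Package: pcrkit
Title: Primer, Probe and Assay Design Toolkit for PCR, LAMP, KASP and
    Gibson Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale toolkit for oligonucleotide analysis and
    PCR assay design. Implements nearest-neighbor melting temperature
    calculation with degenerate-base averaging and salt/magnesium
    correction, linguistic (alphabet-capacity) sequence complexity,
    primer-dimer screening by gapless local alignment with 3'-end and
    central run rules, candidate primer enumeration and pair ranking,
    hydrolysis (TaqMan/MGB) probe design, multiplex and tiling panel
    assembly, k-mer seeded in silico PCR on linear and circular
    templates, LAMP primer-set design with loop primers, allele-specific
    (KASP-style) genotyping assay design, Gibson assembly junction
    primer design, and de novo k-mer repeat identification, masking and
    clustering. Includes a deterministic synthetic-sequence generator
    for reproducible testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
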