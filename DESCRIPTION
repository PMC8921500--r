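Package: asqdesign
Title: Allele-Specific Competitive-Extension PCR (KASP/ASQ) Assay Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design engine for allele-specific competitive-extension PCR
    genotyping assays (KASP/PACE/ASQ). From template sequences carrying SNP
    or InDel polymorphic sites (bracket or IUPAC notation, up to four
    alleles per site), designs thermodynamically equalized allele-specific
    primers with FRET-cassette tails and a common reverse primer.  Includes
    nearest-neighbor melting-temperature and free-energy calculators under
    PCR ionic conditions, linguistic-complexity and G-quadruplex screens,
    primer-dimer/hairpin/binding-site interaction analysis, a four-channel
    universal FRET-cassette system with custom-cassette design, multiplex
    compatibility reporting, and tabular export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
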