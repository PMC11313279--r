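Package: polytg
Title: Genotyping the CFTR Poly-T/TG Tract from Bidirectional Sanger
    Chromatograms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the (TG)mTn ("poly-T/TG") genotype of the CFTR intron 9
    tract from paired forward and reverse Sanger chromatograms in ABIF (.ab1)
    format. The tract is located by anchoring on its 15 bp flanking
    sequences, candidate genotypes over a user-defined search space are
    screened for compatibility with the observed per-position relative
    signal intensities, and survivors are ranked by a normalized difference
    score (lower is better). Includes a bit-exact ABIF reader/writer, a
    seeded chromatogram simulator for heterozygous tract superposition with
    noise and channel bleed-through, plotting of observed versus expected
    peak patterns, JSON reporting, batch operation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
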