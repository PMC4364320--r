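Package: lmwgs
Title: Gene-Family Genotyping, Annotation and Diversity Analysis for
    Low-Molecular-Weight Glutenin Subunits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the low-molecular-weight glutenin subunit
    (LMW-GS) gene family in diploid wheat populations. Provides a synthetic
    sequence generator emulating LMW-GS gene architecture (signal peptide,
    i/m/s-type diagnostic N-termini, glutamine/proline-rich repetitive domain,
    three cysteine-bearing C-terminal domains), in-silico fragment genotyping
    with three conserved primer sets, ORF and pseudo-gene annotation with
    domain segmentation and molecular weight / isoelectric point estimation,
    identity-based clustering of cloned sequences into genes and named allelic
    variants, population genotype and geographic diversity tabulation, and
    distance-based neighbor-joining phylogenies. Ships an encoded fixture of a
    published 157-accession Triticum urartu Glu-A3 genotype table for
    desk-scale reproduction of its population statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    tibble,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
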