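Package: whiteflyCOI
Title: Whitefly mtCO1 Barcode Screening, Species Delimitation and Host
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for partial mitochondrial cytochrome
    oxidase I (mtCO1) barcodes of Bemisia whiteflies. Screens Sanger
    amplicons for nuclear mitochondrial pseudogenes (NUMTs) and PCR
    artefacts by reference-panel alignment, indel detection, trimming to
    the 651-bp barcode window and invertebrate-mitochondrial translation;
    computes p-distances, percent identities and Tajima-Nei corrected
    distances; assigns barcodes to known species or delimits novel
    putative species at a 4 percent divergence threshold with SSA1
    subgroup calls; and builds host-plant by species count matrices for
    composition, minimum-support association and hierarchical clustering
    analyses with validity-index optimal-k selection and multiscale
    bootstrap (approximately unbiased) cluster support. Includes a
    ground-truthed synthetic data generator for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    cluster,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
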