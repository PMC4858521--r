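Package: T4PCensus
Title: Comparative-Genomics Census of Archaeal Type IV Pili Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies archaeal type IV pili (T4P) and archaellum
    systems from genome gene tables by iterative gene-neighborhood expansion from
    secretion-ATPase seed families, with curation based on sequence-feature
    heuristics (class III prepilin signal peptides, transmembrane segments),
    major/minor pilin calling, operon and locus assembly, classification of loci
    against declarative architecture templates, phyletic pattern matrices, and
    multiple-alignment column filtering for phylogeny preparation. Includes a
    synthetic genome-collection generator with planted ground truth so that every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: ComparativeGenomics, Annotation, Classification, Software
RoxygenNote: 7.3.3
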