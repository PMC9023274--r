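Package: capsidMatch
Title: Sequence-Based Prediction of Coat-Protein Binding Sites on +ssRNA
    Viral Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts genomic RNA (gRNA) regions bound by viral coat
    proteins (CPs) from primary sequence alone. Implements smoothed
    nucleobase-density profiles over gRNA triplets and nucleobase-affinity
    profiles over CP residues, sliding-window Pearson correlation between
    the two (profile matching), a linearly additive relative
    interaction-energy model for the unstructured gRNA/CP complex with
    z-scored profiles and lowest-percentile region prediction, and
    statistical evaluation against reference binding sites via
    binding-site coverage with composition-preserving shuffle permutation
    tests. Includes a seeded synthetic gRNA/CP generator with planted
    binding regions, and batch screening of annotated coat-protein
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, SequenceAnalysis, MotifDiscovery, Virology
RoxygenNote: 7.3.3
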