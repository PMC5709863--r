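Package: decontree
Title: Decision-Tree Decontamination of De Novo Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and removes contaminant scaffolds from de novo
    eukaryotic genome assemblies. Computes eight per-scaffold predictor
    variables (length, GC content, and DNA/RNA alignment depth, breadth and
    aligned-read GC), derives target/contaminant training labels from
    tabular BLAST results, trains classification-tree models (single CART
    trees with Gini or entropy splitting, bootstrap-aggregated trees,
    random forests, and boosted shallow trees) and classifies every
    scaffold, including those without database hits. Includes
    confusion-matrix evaluation with training-fraction and predictor-subset
    replicate sweeps, a synthetic contaminated-assembly generator for
    validation, and an end-to-end pipeline that writes a decontaminated
    FASTA and a classification report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
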