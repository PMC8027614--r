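Package: svharvest
Title: Harvesting Large Structural Variants from Whole-Genome
    Resequencing of Mutagenized Strains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and triage of large (>= 50 bp) structural variants
    (deletions, tandem duplications and multiplications, insertions,
    complex deletion-insertions, inversions, translocations) from
    single-end whole-genome resequencing of mutagenized strains.
    Combines split-read breakpoint detection (soft-clip extraction and
    realignment) with binned copy-number-ratio analysis against a control
    strain, calls zygosity from variant frequency, subtracts background
    variants shared across strains, annotates calls against gene models
    and regulatory regions, filters false positives with classical
    machine-learning classifiers, and extrapolates genome-wide mutation
    counts from reporter-assay rates. Includes a deterministic genome,
    variant and read simulator so the whole stack is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    MASS,
    class,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    withr,
    jsonlite,
    knitr,
    rmarkdown
biocViews: StructuralVariation, CopyNumberVariation, Sequencing,
    Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
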