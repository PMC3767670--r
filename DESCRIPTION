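Package: neuropilScreen
Title: Texture-Based Screening of Neuropil-Enriched Transcripts in
    Hippocampal ISH Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for ranking genes by neuropil
    enrichment of their transcripts in high-resolution in situ
    hybridization (ISH) sections of the mouse hippocampus. The pipeline
    localizes Ammon's horn and dentate gyrus with a deformable shape
    model fitted by Differential Evolution, partitions the structures
    into 13 named sub-regions with random-forest quality control,
    describes each section by a 220-dimensional first- and second-order
    (gray-level co-occurrence) texture vector, selects a consensus
    feature subset with a binary genetic algorithm under a silhouette
    fitness, and ranks genes by Pearson correlation to a prototype
    vector averaged over positive training genes. A synthetic ISH
    section generator with known ground truth makes every stage testable
    without external image corpora, and a small qPCR helper implements
    2^-dCt quantification with synaptosome/brain enrichment ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    randomForest,
    png,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification,
    FeatureExtraction, GeneExpression
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'preprocess.R'
    'optim.R'
    'localize.R'
    'neuropilScreen-package.R'
    'selection.R'
    'ranking.R'
    'texture.R'
    'segment.R'
    'synthetic.R'
    'pipeline.R'
    'qpcr.R'
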