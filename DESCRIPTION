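Package: ecmforest
Title: Extracellular Matrix Protein Prediction from Hybrid Sequence Features
    with an Undersampling Random Forest Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies extracellular matrix (ECM) proteins from amino-acid
    sequences and auxiliary per-residue profiles. Encodes each protein as a
    315-dimensional hybrid feature vector combining sequence composition
    (functional-group frequencies, Shannon entropies, distribution and
    transition descriptors), physicochemical properties (pseudo amino acid
    composition and discrete-wavelet-transform statistics of property
    signals), evolutionary information (position-specific scoring matrix
    descriptors) and structural information (disorder, secondary structure
    and functional-domain features). Ranks features by information gain
    ratio, selects an operating subset by incremental feature selection
    against cross-validated balanced accuracy, and classifies with an
    undersampling random-forest ensemble that partitions the majority class
    across forest members and combines them by majority vote, addressing the
    roughly 11:1 class imbalance typical of ECM datasets. Includes readers
    for the standard external file formats (FASTA, PSI-BLAST ASCII PSSM,
    PSIPRED ss2, disorder and domain tables) and a deterministic synthetic
    dataset generator so the whole pipeline can be exercised without
    external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
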