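Package: epitree
Title: Class-Restricted Linear B-Cell Epitope Prediction with K-mer
    Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts linear B-cell epitopes within a single protein class
    by decomposing antigen sequences into frame-shifted k-mers (3 to 15
    residues), labelling each k-mer by a majority-overlap rule against
    curated epitope annotations, describing it with 33 physicochemical
    attributes (amino-acid and charge-group composition, GRAVY, aliphatic
    index, atomic composition, isoelectric point), rebalancing classes
    with SMOTE and training a CART decision tree.  Per-k-mer predictions
    are aggregated to per-residue score tracks from which epitope regions
    are called at a score cutoff and expanded to synthesis-ready
    peptides.  Includes per-residue ROC evaluation under several cutoff
    policies, SPOT peptide-array reactivity tracks, pairwise global
    alignment percent-identity matrices, and a synthetic antigen
    generator with compositionally enriched planted epitopes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    randomForest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
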