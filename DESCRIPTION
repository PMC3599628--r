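Package: idrboost
Title: Prediction of Intrinsically Disordered Protein Regions with
    Boosted Ensembles of Deep Belief Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based prediction of intrinsically disordered
    protein regions. Residues are encoded from sliding windows over
    position-specific scoring matrices, predicted secondary structure,
    predicted solvent accessibility and Atchley physicochemical factors;
    classified by deep networks pretrained layer-wise as restricted
    Boltzmann machines (contrastive divergence) and fine-tuned by
    backpropagation; and combined by a modified AdaBoost procedure with
    periodic weight reinitialization, followed by averaging across
    window-size ensembles and optionally with an external score track.
    Includes a CASP-style evaluation suite (balanced accuracy, Sw,
    F-measure, ROC/AUC, bootstrap standard errors), a synthetic dataset
    generator with disorder-coupled features for desk-scale training and
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
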