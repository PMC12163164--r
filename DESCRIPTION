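Package: hazcp
Title: Conformal Prediction of Chemical Hazard Classes from SMILES N-Grams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary hazard-statement (CLP/GHS H-statement) classification
    with confidence. Molecules given as SMILES strings are featurized by
    dictionary-based N-gram hashing (raw SMILES, pair-encoded tokens,
    DeepSMILES and SELFIES-style transforms) or by circular fingerprints,
    then classified by a random forest wrapped in a Mondrian inductive
    conformal predictor that yields class-conditional p-values and
    four-outcome prediction sets with a user-chosen error rate. Includes
    median-p-value and majority-vote consensus models, a cross-validated
    evaluation harness (validity, efficiency, balanced accuracy, MCC,
    ROC-AUC), and a synthetic data generator with planted toxicophore
    motifs, class imbalance, salts and label noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
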