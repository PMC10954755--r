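Package: readthroughr
Title: Stop Codon Readthrough Quantification, Context Modeling, and
    Nonsense Allele Readthrough Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptome-wide analysis of stop codon
    readthrough from ribosome profiling region counts. Quantifies
    readthrough efficiency as the log2 ratio of extension-region to
    coding-region RPKM, encodes the extended stop codon context
    (stop codon, flanking nucleotides, P-/E-site codons, nascent
    peptide exit tunnel properties, region lengths) into model
    features with randomized negative controls, trains random forest
    regression and classification models with cross-validated mtry
    selection and out-of-bag permutation importance, runs grouped
    median comparisons, chi-squared association tests, and Spearman
    correlation analyses of readthrough determinants, folds 3'-UTRs
    to obtain lowest local minimum free energies, predicts premature
    termination codon readthrough from native or reporter-embedded
    contexts, and processes dual-luciferase reporter plate data.
    Includes a synthetic data generator with planted context effects
    so the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
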