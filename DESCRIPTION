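Package: nfomics
Title: Paired Serum Metabolome and Gut Microbiome Analysis of Neutropenic Fever
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal paired-omics studies of neutropenic fever in
    chemotherapy patients: pre/post-fever labeling and preprocessing of serum
    metabolite matrices (detectability filtering, half-minimum imputation),
    unsupervised structure and univariate screening (PCA, Bray-Curtis PERMANOVA,
    Welch tests with Benjamini-Hochberg correction, complete-linkage clustering),
    sparse partial least squares discriminant analysis with cross-validated tuning,
    stability selection and leave-one-out ROC, stool count-table quality control
    with scaling-by-ranked-subsampling depth normalization and Aitchison beta
    diversity, serum-stool sample pairing, and genus-metabolite association
    discovery by zero-sum-constrained sparse log-contrast regression with
    bootstrap stability selection. Includes a synthetic cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    jsonlite,
    optparse,
    biomformat
Config/testthat/edition: 3
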