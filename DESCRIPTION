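Package: paca
Title: Phenotype Aware Component Analysis for Case-Control Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Contrastive dimensionality reduction for high-dimensional
    case/control omics matrices (e.g. DNA-methylation beta values).
    Shared sources of variation between cases and controls -- cell
    composition, batch, ancestry -- are estimated by canonical
    correlation analysis carried out in sample space, projected out of
    the case matrix, and the residual principal components capture
    case-specific latent structure. Includes a permutation scheme for
    choosing the number of shared directions to remove, a randomized
    variant for the more-samples-than-features regime, export of a
    component as a portable patient-stratification score projectable
    onto new cohorts, a contrastive-PCA baseline, a synthetic-data
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
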