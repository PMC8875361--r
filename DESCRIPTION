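Package: sigregulon
Title: Sigma-Factor Regulon Assignment from Mutant-Panel RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strain-comparative transcriptome analysis for a cyanobacterial
    group 2 sigma-factor mutant panel. Provides a self-contained
    negative-binomial differential-expression stage (median-of-ratios
    normalization, method-of-moments dispersion, two-group Wald test,
    Benjamini-Hochberg adjustment), combinatorial regulon-assignment rules
    that classify genes into SigB, SigD or SigC-or-E regulons per growth
    condition from the pattern of significant calls across four deletion
    strains, cross-condition regulon comparison, a negative-binomial count
    simulator with planted sigma-factor-dependent effects for end-to-end
    validation, and small utilities for promoter-reporter activities and
    dilution-corrected growth curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), MASS, DESeq2, withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
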