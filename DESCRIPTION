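Package: bilfreqsel
Title: Gene Selection Frequency and QTL Mapping for Backcross Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies transcripts associated with a quantitative trait in
    small backcross-inbred-line (BIL) populations by repeated L1-penalised
    regression on random subsets of the transcriptome (gene selection
    frequency), and maps quantitative trait loci (QTL) and expression QTL
    (eQTL) by regression-based composite interval mapping with
    permutation-derived LOD thresholds and Kosambi map distances. Includes
    FPKM filtering and log transformation, Pearson/ANOVA association
    statistics, absolute qPCR quantification from standard curves, and a
    synthetic BIL data generator with planted ground truth so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
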