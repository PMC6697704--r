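Package: hgfmet
Title: Mechanistic Modeling of HGF/Met Signaling with Integrin-Dependent Receptor Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistically detailed ordinary-differential-equation model of
    hepatocyte growth factor (HGF) signaling through the Met receptor tyrosine
    kinase, including alpha5beta1-integrin-dependent receptor trafficking
    (internalization, degradation, recycling) and the downstream Akt and ERK
    cascades with their feedback loops, together with the analysis workflow
    around the model: derivative-free pattern-search calibration to normalized
    phospho-protein time courses, Monte-Carlo resampling uncertainty
    quantification and practical-identifiability classification,
    Latin-hypercube / partial-rank-correlation (LHS-PRCC) global sensitivity
    analysis, dose-response and MuSyC two-drug synergy-surface quantification
    for the integrin-binding peptide AXT050 combined with sorafenib,
    cabozantinib, and rilotumumab, and virtual-patient cohorts built by scaling
    protein abundances with tumor/normal expression fold changes. Includes
    SBML import/export and synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
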