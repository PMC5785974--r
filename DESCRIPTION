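Package: mitoapop
Title: Mitochondrial Content and Cell-to-Cell Variability in TRAIL-Induced Apoptosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fractional killing of clonal cell populations exposed to
    TRAIL with a mass-action ordinary differential equation model of the
    extrinsic apoptosis pathway. Cell-to-cell variability enters through
    ensembles of initial protein copy numbers sampled from log-normal
    distributions that co-vary with a per-cell mitochondrial content variable.
    Provides the fate rule based on the maximum Caspase-8 activation rate, the
    Smac-release definition of time to death, receiver operating characteristic
    analysis of single-variable fate classifiers, the mitochondrial
    contribution to variability (MCV) statistic with linear de-trending,
    dispersion measures with bootstrap confidence intervals, correlation
    sensitivity and sweep experiments, expression-table processing
    (FPKM to TPM, per-cell correction, detection-threshold flooring), and
    seeded synthetic-data generators for imaging-style and
    immunofluorescence-style single-cell tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
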