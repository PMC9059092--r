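Package: prefulr
Title: Phase-Resolved Functional Lung MRI Ventilation and Perfusion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for phase-resolved functional lung (PREFUL)
    MRI of free-breathing dynamic proton acquisitions. Separates respiratory
    and cardiac signal components by zero-phase temporal filtering, sorts
    frames into equidistant respiratory (60-phase) and cardiac (30-phase)
    cycles, and derives regional ventilation (RVent) maps, flow-volume-loop
    correlation maps (FVL-CM), quantitative perfusion in mL/min/100 mL,
    defect percentages, and ventilation-perfusion match metrics. Includes a
    synthetic phantom generator with ground truth, a simulated two-period
    crossover trial generator, and least-squares-means crossover
    treatment-effect estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
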