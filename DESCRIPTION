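Package: chemoICB
Title: Tumour-Immune Dynamics Under Chemotherapy and Immune Checkpoint Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled deterministic and stochastic models of tumour evolution under
    immune selection, for antigenically homogeneous and heterogeneous tumours.
    Implements predator-prey style compartment models of neutral, antigenic,
    immunogenic and immune-escaped cancer cells with negative frequency-dependent
    immune recognition, square-wave pharmacokinetics for pulsed chemotherapy and
    immune-checkpoint-blockade (ICB) dosing, a per-cell branching-process simulator
    that tracks neoantigen accumulation, and scripted in-silico therapy experiments:
    growth and immune-escape dynamics, mono- and combination-therapy response
    regimes, neoantigen Shannon-diversity analyses, dose-pair response grids,
    parameter sensitivity, and alternating chemo-then-ICB protocols with an
    immune-recovery healing factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
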