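Package: udshift
Title: Utilization-Distribution Overlap Analysis of Wildlife Range Shift
    Under a Growing Disturbance Footprint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify spatially explicit shifts in the seasonal
    distribution of GPS-collared wildlife populations relative to a growing
    anthropogenic disturbance footprint, a baseline-era range, and static
    habitat. Estimates individual and population utilization distributions
    (UDs) by fixed-kernel density with per-axis plug-in bandwidths on a shared
    250-m grid, treats the cumulative disturbance footprint's moving-window
    density as a pseudo-UD, computes the PHR and UDOI overlap indices, and
    regresses overlap and individual behavioural metrics on year and an
    interannual climate index with linear and mixed models. Includes a
    synthetic-data generator (landscape, migratory telemetry, growing
    footprint, climate series) with known ground truth, season delineation by
    recursive partitioning of daily movement rates, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    KernSmooth,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
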