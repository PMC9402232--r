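Package: catchbond
Title: Force-Dependent Bond Lifetime Models for Single-Molecule Force Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule optical-trap measurements of
    receptor-ligand bonds under load, motivated by the cadherin-catenin/F-actin
    linkage. Implements Bell-Evans force-dependent rate laws and three candidate
    bond-lifetime models (one-state slip, two-state slip mixture, and a two-state
    catch bond treated as a first-passage problem on a two-bound-state Markov
    chain), maximum-likelihood fitting with a genetic-algorithm global search and
    a zero-force mean-lifetime constraint, AIC/BIC model comparison, empirical
    bootstrap confidence intervals and mean-lifetime envelopes, change-point and
    spectral detection of binding events in raw trap traces, sliding-window
    lifetime-ratio and filament directionality statistics, and a synthetic-data
    generator (analytic inverse-CDF and Gillespie samplers, multi-step rupture
    events, raw trace synthesis) so every stage can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    survival,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
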