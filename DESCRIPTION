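Package: grainqual
Title: Grain Protein and Starch Quality Simulation for Foxtail Millet
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates post-anthesis grain protein and starch accumulation in
    foxtail millet from daily crop-state trajectories (biomass, nitrogen,
    transpiration, temperature) such as those produced by process-based crop
    growth models. Grain protein is obtained from grain nitrogen through a
    stress-modulated nitrogen-to-protein conversion factor; grain starch is
    accumulated per grain with Michaelis-Menten kinetics limited by enzyme
    activity responses to thermal time, cardinal temperatures and water and
    nitrogen stress, and partitioned into amylose and amylopectin. Includes a
    seeded synthetic trajectory generator, genetic-algorithm parameter
    calibration against RMSE, and MRD/RMSE/NRMSE model-evaluation statistics
    with the standard four-category NRMSE classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
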