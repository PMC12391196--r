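Package: kneelax
Title: Subject-Specific Knee Ligament Calibration from Laxity Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for calibrating subject-specific tibiofemoral
    models against knee laxity measurements. Provides Grood-Suntay joint
    coordinate kinematics, nonlinear tension-only ligament fibers with a
    quadratic toe region, tri-linear condylar contact, a quasi-static
    equilibrium solver with flexion/load continuation, laxity and pivot-shift
    simulation protocols, a grouped percentile-weighted calibration cost with
    two-phase particle-swarm plus Nelder-Mead optimization, and a synthetic
    knee generator with known ground truth for end-to-end replication
    experiments comparing in vivo style (KLA) and in vitro style (RKS)
    calibration target sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    withr,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
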