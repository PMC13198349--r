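Package: lpmcollide
Title: Collision Risk Modeling for Leadless Pacemaker Implantation in the
    Right Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual implantation of leadless pacemakers (modeled
    as rigid cylinders) across the right-ventricular septum of dynamic
    heart anatomies and quantifies mechanical collision risk with the RV
    free wall, papillary muscles and moderator band, and tricuspid valve
    apparatus over the cardiac cycle.  Provides a parameterized synthetic
    dynamic RV anatomy generator calibrated to end-diastolic volume and
    ejection fraction, exact cylinder versus triangle-mesh collision
    predicates accelerated by a bounding-volume hierarchy, AHA and left
    bundle branch area pacing (LBBAP) regional mapping on a standardized
    septal coordinate grid, volume-preserving device-length design sweeps,
    and cohort-level risk aggregation with length-trend regression and
    paired device comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
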