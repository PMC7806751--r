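Package: nemacensus
Title: Census of Nematode Skin Epibionts from Semi-Quantitative Scrape Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates densities, community composition, prevalence and
    whole-animal loads of skin-dwelling nematode epibionts from
    semi-quantitative (ordinal 0/+/++/+++) skin-scrape surveys of large
    aquatic mammals. Implements ordinal category-to-count conversion, a
    two-stage (within-host, then across-host) density estimator, a
    circle-plus-ellipse dorsal surface-area model driven by curvilinear
    length and umbilicus girth, depth-resampling yield multipliers, and
    geometric extrapolation to per-animal load ranges. Ships audited
    transcriptions of a two-year Florida manatee survey as fixtures and a
    depth-stratified negative-binomial survey simulator with a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
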