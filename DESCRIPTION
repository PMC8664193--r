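Package: ehcaccess
Title: Spatial Accessibility of Emergency Health Care on Road Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes spatial accessibility to emergency health care over a
    routed road network: closest-facility travel times from ambulance
    stations and emergency departments to population-weighted area
    centroids, composition of response time (RT), transportation time (TT)
    and total prehospital time (TPT) with urban/rural activation and
    on-scene constants, golden-hour and quintile classification, and the
    downstream comparative (one-way ANOVA with Tukey post-hoc) and
    disparity (negative binomial regression with a rural-by-older-adults
    interaction) analyses. Includes a seeded synthetic-region generator so
    the full pipeline is testable without restricted national datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    deldir,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
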