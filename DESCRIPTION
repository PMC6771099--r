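Package: regionflow
Title: Patient-Flow Delineation of Hospital Service Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse inter-municipal patient flows for hospital
    regionalization. Builds origin-destination matrices from admission
    records, computes Elzinga-Hogarty LIFO/LOFI sufficiency coefficients
    for municipalities, micro-regions and regions, delimits service areas
    by successive enlargement, represents cross-border flows as directed
    weighted networks (hub identification, hub-excluded subnetworks,
    per-origin destination entropy), and derives catchment-area intensity
    quartiles and displacement statistics from municipal centroids. A
    gravity-model simulator generates realistic admission datasets with a
    dominant hub, distance-decayed destination choice and birth-rate
    driven case volumes, so the whole pipeline is testable without access
    to confidential hospitalization databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
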