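Package: walkshed
Title: Neighbourhood Spatial Indicators of Walkability and Amenity Access
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes neighbourhood-level spatial indicators of urban design
    and transport features on pedestrian street networks: 1000 m walkable
    catchments approximated by a 250 m population grid, binary 500 m network
    access to amenities (healthy food markets, convenience stores, public
    transport stops, public open space entry points), service-frequency-aware
    transit access from GTFS schedules, a daily living score, a composite
    walkability index standardised within or between cities, and
    population-weighted exposure to density thresholds that support physical
    activity. Includes a deterministic synthetic-city generator (street
    network, population grid, destinations, open space, GTFS feed) so the full
    pipeline is testable without downloads, hexagonal neighbourhood
    aggregation, and city benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
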