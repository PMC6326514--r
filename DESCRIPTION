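Package: equitag
Title: Proximity-Tag Contact Networks for Equine Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating, cleaning and analysing contact data from
    proximity-logging RFID tags deployed in an equine boarding facility. A
    schedule-driven facility simulator produces ground-truth per-second
    proximity streams; a tag emulator reproduces the event semantics of
    flash-logging active tags (1 Hz sensing, 30 s washout termination,
    per-tag counter clocks, limited memory, battery depletion, sporadic
    restarts); a cleaning pipeline reconciles the raw per-tag logs into
    contact events; and analysis functions aggregate events into daily
    weighted networks, compute degree, strength and eigenvector centrality,
    assess homogeneous mixing via contact heat maps, and compare tag-derived
    networks against survey-predicted networks with a two-by-two
    classification table (sensitivity, specificity, PPV, NPV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
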