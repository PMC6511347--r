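Package: radargate
Title: Radar Dot-Plot Screening of Acute Promyelocytic Leukemia by Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens acute myeloid leukemia immunophenotyping data for acute
    promyelocytic leukemia (APL) using multidimensional radar (star-coordinate)
    dot-plots. Reads and writes FCS 3.0/3.1 list-mode files for a four-tube,
    eight-color AML panel, projects scaled multi-marker blast populations into
    two-dimensional star coordinates, learns highest-density-region gates from
    merged reference APL cases, and classifies new cases as hypergranular-APL-like,
    microgranular-APL-like, or non-APL from per-tube blast-in-gate percentages and
    in-gate pattern similarity. Includes a seeded synthetic-cohort simulator that
    emulates hypergranular APL, microgranular APL, and NPM1-type CD34-negative
    non-APL AML acquisitions for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
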