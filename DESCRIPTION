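Package: palmccm
Title: Convergent Cross Mapping of Oil-Palm Stem Carbohydrates, Reproductive
    Growth and Cumulative Climate Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Empirical dynamic modelling toolkit for monthly tree-trait time
    series observed on replicate trees: female reproductive organ (FRO)
    volume and growth, stem starch and soluble-sugar contents, and daily
    meteorology condensed into cumulative temperature and rainfall windows.
    Implements dewdrop-style composite standardisation of replicate series,
    segment-aware Takens delay embedding, simplex projection, S-map
    nonlinearity scans, time-lagged convergent cross mapping with
    library-size convergence checks, and twin-surrogate significance
    testing, together with a full analysis pipeline, CSV readers and
    writers, and a synthetic-data generator with known coupling structure
    for validating the inference machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
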