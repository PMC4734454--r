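Package: emobook
Title: Event-Driven Agent-Based Simulation of Emotional Bookkeeping in
    Macaque-Like Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A continuous-time, spatially explicit agent-based simulator of
    small macaque-like social groups in which dynamic, partner-specific
    emotional attitudes (LIKE) accumulate satisfaction from received grooming
    and decay with a configurable half-life, and in which partner selectivity
    biases affiliation toward highly LIKEd partners.  Includes the full
    analysis layer for grooming relationships: dyadic sociomatrices, hourly
    grooming rates, preferred-partner bout statistics, row-wise Pearson
    matrix correlation with Fisher-z pooling, and row-wise Kendall tau
    reciprocity, plus tools to sweep the memory-decay and selectivity
    parameter grid across replicate runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
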