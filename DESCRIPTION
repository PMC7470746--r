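Package: crossfeedr
Title: Chemostat Cross-Feeding Models and Metabolite Release Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying metabolite cross-feeding between microbial
    auxotrophs in continuous culture. Implements a releaser-consumer
    consumer-resource model of organosulfur (glutathione-equivalent) release
    and consumption with its steady-state ratio prediction, per-cell release
    rate estimation from chemostat steady states, dead-cell lysis attribution,
    continuous-culture device math, chromatogram peak picking with
    local-minima baseline correction and standard-curve quantification,
    yield- and rate-based tester-strain bioassays, sliding-window growth and
    death kinetics, log-ratio competition fitness with frequency-dependence
    summaries, and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
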