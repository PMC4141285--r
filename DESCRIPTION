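Package: pcmsim
Title: Simulation and Exact Analysis of the Pairwise-Competition Model of
    Serial-Position Effects in Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how serial position shapes constructed
    preferences under the pairwise-competition model, a sequential updating
    process in which each newly encountered option challenges the current
    favorite and survives with a probability given by Luce's choice rule,
    attenuated by static or dynamically increasing choice inertia. Provides
    a vectorised Monte-Carlo simulator, exact solvers (closed form for
    equal-quality sequences, dynamic programming over fixed or discretised
    quality distributions), a full factorial sensitivity-analysis driver with
    reproducible per-condition random streams, primacy/recency effect
    summaries against the random-choice baseline, tidy CSV persistence, and
    ggplot2 figures of serial-position preference curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
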