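Package: sedrisk
Title: Probabilistic Ecological Risk Assessment of Potentially Toxic Elements in River Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the ecological risk posed by potentially toxic
    elements (PTEs) in river sediments. Summarises five-step sequential-extraction
    (modified Tessier) data into fraction percentage profiles, mobility orderings
    and retention-based contamination factors; computes deterministic Hakanson
    single-factor (Er) and total (RI) ecological risk indices with their standard
    risk classes; and replaces single-point risk estimates with seeded Monte Carlo
    simulation over fitted concentration distributions, yielding risk-class
    probability tables and exceedance probability curves. A synthetic-study
    generator with known ground truth makes every pipeline stage testable when
    per-sample field data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
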