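Package: asterchain
Title: Life-History Aster Chain Models and Phenotypic Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint likelihood analysis of sequential fitness components
    ("aster" chain models): annual survival modelled as Bernoulli nodes
    conditioned on their predecessor and final height as a terminal normal
    node conditioned on survival. Supports fixed-effect maximum likelihood
    and Laplace-approximate mixed-effect fits with random intercepts for
    field-design groupings (block, maternal family, row-plot), prediction
    of cumulative survival and of unconditional expected height (the
    fitness measure that accounts for mortality as structural zeros),
    likelihood-ratio tests between nested fits, Spearman multicollinearity
    screening, forward-stepwise estimation of linear, quadratic and
    correlational selection gradients, fitness-surface grids with
    selection-form classification, and a calibrated simulator of
    common-garden drought experiments with exported ground truth for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr
Config/testthat/edition: 3
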