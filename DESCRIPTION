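Package: mixsel
Title: Expected Responses to Recurrent Selection for Performance in Species Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical machinery for predicting one-cycle responses to
    recurrent selection of two plant species bred for performance in mixture.
    Implements the general/specific mixture-ability (GMA/SMA) decomposition of
    mixture performance, expected responses under three schemes (reciprocal
    mixture-ability selection, parallel general mixture-ability selections,
    and parallel pure-stand selections), selection-index tuning to control the
    responses of the two species contributions, constrained optimization of
    index pairs, and a Monte-Carlo truncation-selection simulator that serves
    as an independent check of every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
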