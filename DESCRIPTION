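Package: picoscreen
Title: Machine-Assisted Abstract Screening with PICOS Exclusion Reasons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-assisted title/abstract screening in systematic
    literature reviews. Citations are classified by a two-stage cascade: an
    overall include/exclude text classifier followed by pairwise
    include-versus-reason classifiers, resolved through a probability
    threshold and a fixed PICOS hierarchy into include, exclude with a stated
    reason, or unclassified (returned to a human reviewer). Includes
    bag-of-words feature generation with frequency and importance filters,
    class balancing by downsampling, cross-validated hyperparameter tuning
    for support vector machine, naive Bayes and bagged CART learners, a
    factorial simulation harness with paired comparisons, and a synthetic
    citation-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    e1071,
    rpart,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
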