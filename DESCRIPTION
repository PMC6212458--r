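Package: vpalloc
Title: Variable-Precision Models of Working Memory Resource Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modeling how visual working memory resource is split
    across items of unequal behavioral relevance. Implements the
    variable-precision generative model of memory-guided saccade errors
    (gamma-distributed precision, Rayleigh error magnitudes), four resource
    allocation strategies (Proportional, Flexible, Minimizing Error,
    Maximizing Points), an expected-utility model of post-decision wagers
    with softmax decision noise, maximum-likelihood fitting with AICc/BIC
    model comparison, parameter and model recovery, model-free behavioral
    statistics with stratified permutation nulls, and a task-design-faithful
    synthetic data generator for the priority memory-guided saccade paradigm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
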