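Package: fosconnect
Title: cFos Activation Mapping and Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for immediate-early-gene (cFos) brain
    activation mapping studies. Aggregates per-section cFos-positive cell
    counts into per-animal regional densities, compares experimental groups
    by one-way ANOVA with Sidak or Holm-Sidak post-hoc correction, computes
    per-group inter-regional Pearson correlation matrices with
    pairwise-complete observations and a minimum-pair exclusion rule, and
    builds thresholded functional-connectivity networks with fold-change
    node weights and degree-based hub ranking. Includes a synthetic cohort
    generator with planted group means and inter-regional correlation
    structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
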