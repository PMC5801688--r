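Package: phiscan
Title: Non-Parametric Discovery and Validation of Genomic Markers of Drug
    Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers genomic markers of in vitro drug sensitivity from
    cell-line screening panels without distributional assumptions. For each
    drug-gene association a mutation-dependent logIC50 threshold (the mean
    of the mutant and wild-type median responses) converts the association
    into a binary classification problem; discriminative power is measured
    by the phi coefficient (Matthews correlation coefficient) and its
    significance by Pearson's chi-squared test with one degree of freedom,
    exploiting the identity chi-squared = n * phi^2. Benjamini-Hochberg
    control selects significant associations, optionally intersected with
    an external p-value set for consensus calls, and surviving markers are
    validated by their MCC on held-out cell lines using a drug-level median
    sensitivity threshold. Includes a reproducible synthetic-panel
    generator with planted drug-gene effects for power and type-I-error
    studies, and a command-line pipeline (simulate, discover, validate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
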