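Package: fcmdiv
Title: Cognitive Diversity Analysis for Fuzzy Cognitive Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying cognitive diversity within and between
    groups of stakeholders from fuzzy cognitive maps (FCMs).  Implements a
    combined Jaccard/spectral cognitive-distance measure on weighted directed
    concept graphs, intra- versus inter-group comparison statistics, a
    Monte-Carlo generator of virtual agents from empirical edge
    distributions, Shannon-entropy identity-diversity indices, and
    micro-motif (directed graphlet) profiling with PCA and k-means
    clustering.  Includes a synthetic-population generator with controllable
    between-group separation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
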