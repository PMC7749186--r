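Package: opanet
Title: Growing Network Models Generating Dense Scale-Free Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulators and theory for a family of growing network models
    based on ordinal preferential attachment (OPA): the degree-copying
    model with the classical OPA link rule, its adjunction-rule variant,
    a neighborhood-OPA model derived from a Galois-connection argument,
    and the duplication-divergence copying baseline.  Includes the
    rate-equation predictions for the degree exponent and link-count
    scaling, ensemble network statistics (degree distribution, power-law
    exponent fits, degree-degree correlation, degree-dependent local
    clustering), and an executable verifier for the Galois-connection
    laws on the degree preorder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
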