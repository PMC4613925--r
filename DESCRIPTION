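Package: carevol
Title: Evolutionarily Stable Biparental Care in Quality-Structured Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for the evolution of biparental
    care when parental quality is itself set by the care an individual
    received as an offspring (a transgenerational parental effect). The
    population is structured into good and poor parents; care levels are a
    four-component sealed-bid strategy (own quality x partner quality).
    The package computes the demographic fixed point, normalized brood
    productivities, the competitiveness-mediated quality transition,
    class reproductive values by eigenanalysis of a 2x2 projection matrix,
    selection gradients on mutant care, and evolutionarily stable care
    levels by gradient-ascent iteration, with and without sexual conflict
    (coparents genetically identical). An individual-based Monte Carlo
    simulator of the same life cycle serves as an independent cross-check
    and as a stochastic evolution oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
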