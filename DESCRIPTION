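Package: duckNE
Title: Net Energy Evaluation of Feed Ingredients for Growing Ducks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for determining the net energy (NE) of feed ingredients for
    growing ducks by the comparative-slaughter energy-balance method. The
    package converts per-replicate trial records into metabolizable energy
    intake, retained energy and heat production per unit metabolic body
    weight, estimates fasting heat production (and hence the maintenance net
    energy requirement) by log-linear regression of heat production on intake
    with extrapolation to zero intake, extracts ingredient NE by the
    difference (substitution) method, and builds NE prediction equations from
    grain chemistry by correlation screening and classical stepwise multiple
    regression. A seeded synthetic-data module generates wheat chemistry
    panels and feeding/substitution trials with a prescribed moment and
    correlation structure so the whole pipeline can be exercised and validated
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
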