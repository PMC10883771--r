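Package: serialrumen
Title: Analysis of Serially Transferred Rumen Mixed Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational layer for serially transferred rumen in vitro
    batch cultures run at contrasting average dilution rates: dilution-rate
    design arithmetic, headspace gas quantification (CH4, H2, H2 partial
    pressure) with residual-air correction, carryover-corrected net
    metabolite production, a discrete growth-dilution model estimating
    microbial replication rates and doubling times from marker-gene copies,
    13C isotopolog enrichment of volatile fatty acids in delta notation,
    absolute qPCR copy quantification from dsDNA fragment standards, the
    factorial mixed-model design with unequal-spacing polynomial contrasts
    and a studentized-residual outlier rule, and a synthetic serial-culture
    simulator with known ground truth so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
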