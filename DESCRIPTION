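Package: BoolGMN
Title: Boolean Gene-Modular-Network Analysis of Morphogen-Patterned Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses Boolean gene-modular networks (GMNs) from
    position-resolved expression profiles along a morphogen gradient, as in the
    anterior-posterior axis of the Drosophila wing imaginal disc. Provides
    monotone-trend screening of morphogen-responsive genes, batch integration
    of staggered sample sets, hierarchical module construction and
    binarization, Boolean rule inference from spatial state sequences,
    exhaustive attractor/basin and state-transition-tree analysis, and two
    robustness studies: random bit-flip perturbation of the observed state
    table and morphogen-production (boundary-shift) scans. A seeded synthetic
    data generator emulating modular positional expression makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
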