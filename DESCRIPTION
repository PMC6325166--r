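Package: pblipidr
Title: Carbon-Carbon Double-Bond Localization in Glycerophospholipids from
    Paterno-Buchi Tandem Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies unsaturated glycerophospholipids at the carbon-carbon
    double-bond (C=C) location level from liquid-chromatography tandem mass
    spectrometry data acquired after online Paterno-Buchi (PB) photochemical
    derivatization with acetone. Provides exact monoisotopic mass arithmetic and
    lipid formula templates, headgroup-specific neutral-loss/precursor-ion scan
    profiling, fatty acyl chain assignment from negative-mode MS/MS, in-silico
    prediction of the aldehyde/olefin diagnostic fragment-ion pairs produced by
    collision-induced dissociation of PB products, de novo C=C position
    assignment with relative quantitation of C=C location isomers, and a
    biomarker statistics layer (group comparisons with false-discovery control,
    variance decomposition, hierarchical clustering of isomer-ratio matrices).
    Includes a seeded simulator that emulates the three scan layers of the
    workflow for a user-specified ground-truth lipidome, used throughout the
    test suite and documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
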