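Package: sibcut
Title: BCUT Descriptor Modeling of siRNA Gene-Silencing Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity modeling of siRNA gene-silencing
    potency from the chemical structures of the composing nucleotides. Each
    nucleotide monomer is described by twelve BCUT descriptors (eigenvalue
    summaries of Burden connectivity matrices weighted by Gasteiger PEOE
    partial charges and Wildman-Crippen logP and molar-refractivity atomic
    contributions), and a 21-mer guide strand is encoded as the concatenation
    of the per-position descriptor blocks. Models are fit by NIPALS partial
    least squares on rationally designed train/test pairs obtained from ART-2a
    adaptive-resonance clustering, with multi-split evaluation, principal
    component scans, training-size scans, y-scrambling and descriptor
    relative-importance analyses. Supports both natural and chemically
    modified nucleotide alphabets, and ships a synthetic benchmark generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
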