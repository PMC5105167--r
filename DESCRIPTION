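Package: glyconms
Title: Pseudo-Native Mass Spectra and Biosimilarity Scoring for Intact Glycoproteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs pseudo-native mass spectra of intact glycoproteins from
    site-specific modification tables (glycan compositions and relative
    abundances) under an independence model, projects proteoform mass
    distributions through an electrospray charge envelope into m/z space, and
    scores the similarity of native mass spectra by Pearson correlation of
    binned intensities with a principled bin-width selector. Also assigns
    overall glycan/PTM compositions to measured intact-protein masses by
    bounded integer search within a mass tolerance, simulates in-silico
    sialidase and PNGase F treatments, and generates synthetic ground-truth
    models and noisy spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
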