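Package: skinmorph
Title: Epidermal Histomorphometry of Human Skin Surrogate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative comparison of the epidermal
    architecture of human skin and three surrogate models (a reconstructed
    human epidermis, ex vivo pig skin, and rabbit skin). Provides a
    synthetic-section generator with per-column ground truth, QuPath-style
    per-layer thickness morphometry, deposition percentages, a rank-based
    inter-model similarity score, the MKI67 (Ki-67) proliferation index from
    DAB/hematoxylin nucleus tables, and unpaired Student's t-test reporting
    with significance stars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
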