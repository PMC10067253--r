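Package: occlusal3d
Title: Quantitative 3D Occlusal Contact and Bite-Force Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for digital occlusal analysis on intraoral-scan meshes.
    Segments articulating-paper contact marks on a colored dental-arch mesh,
    quantifies occlusal contact area (OCA) and contact number (OCN), registers
    a 2D pressure-film force record onto the projected 3D contacts, and
    computes per-contact and per-tooth occlusal force vectors (resultant and
    x/y/z components) in an anatomically defined occlusal coordinate frame.
    Includes a ground-truthed synthetic arch-mesh generator, method-agreement
    statistics (ICC, Bland-Altman, paired t, Pearson/regression), ggplot2
    visualisations, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
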