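Package: emphysim
Title: Coupled Immune and Biomechanical Simulation of Emphysema Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale simulation of emphysema onset and progression in lung
    parenchyma. Couples a thirteen-variable ordinary differential equation model
    of macrophage polarization, cytokine feedback and matrix remodeling with a
    grid-based agent model of smoking-driven particle deposition and
    inflammation-mediated tissue damage, and with a two-dimensional plane-stress
    finite-element model whose per-element Young's modulus follows the local
    elastin/collagen composition. Over-strained alveolar units rupture and feed
    back into the agent model. Includes a CT-patch layer (parenchyma
    segmentation, seed deposition, modulus-to-Hounsfield remapping, mean lung
    density quantification, a synthetic patch generator) and the standard
    in-silico experiments: smoking-exposure grid, fractional-factorial parameter
    sensitivity, and mean-lung-density progression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    png,
    tiff,
    withr,
    xml2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
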