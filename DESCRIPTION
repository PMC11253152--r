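Package: ependysim
Title: Hybrid Agent-Based and Reaction-Diffusion Simulation of Axolotl
    Spinal Cord Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the regenerating axolotl spinal cord as a growing
    two-dimensional tissue of proliferating hard-disc ependymal cells whose
    cell cycles are accelerated by a diffusing, degrading signal produced at
    the posterior wound front. The signal is solved with a smoothed-particle
    (diffusion-velocity) scheme on the moving domain; cells carry
    non-Markovian cell-cycle clocks (or a simplified Poisson division model)
    and are recruited irreversibly when the local signal density exceeds a
    threshold. The package also provides the closed-form fast
    reaction-diffusion theory of the recruitment limit and outgrowth, curve
    error metrics and grid fitting, and synthetic stand-ins for recruitment
    limit and cell-cycle phase profile datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
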