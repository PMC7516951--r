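Package: dgpop
Title: Dichotomized-Gaussian Population Models of Correlated Neural Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the homogeneous dichotomized-Gaussian (DG) model of
    correlated neural population spiking. Maps latent Gaussian input
    statistics (mean h, pairwise correlation alpha) to output firing
    statistics up to fourth order via multivariate normal orthant
    probabilities, computes the exact finite-population spike-count
    distribution, extracts information-geometric log-linear (theta)
    interaction coordinates, and characterises the model's critical
    behaviour: the UP/DOWN-state bimodality of the asymptotic spike-count
    density at alpha = 1/2 and the Binder-cumulant crossing of the
    temperature-extended model at T = 1. Includes seeded spike-raster
    simulation, empirical cumulant estimators, Shannon entropy and Fisher
    information of the population distribution, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
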