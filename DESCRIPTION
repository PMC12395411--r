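Package: trxps
Title: Transient Core-Level Photoelectron Spectroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing and modelling time-resolved X-ray
    photoelectron spectroscopy (TR-XPS) pump-probe experiments on
    photoexcited molecules, developed around the UV-induced relaxation of
    gas-phase uracil. Provides stick-spectrum broadening and composition of
    transient core-level spectra, closed-form branching population kinetics
    under a Gaussian instrument response (exponentially modified Gaussians),
    a synthetic UV-on/UV-off map generator with sidebands, hot-ground-state
    signatures, coherent vibrational modulation and Poisson noise,
    difference-map and scaled-subtraction reduction with excited-fraction
    estimation, shared-parameter global fitting of region-integrated time
    traces, ground-state peak tracking, and Fourier analysis of coherent
    intensity oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
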