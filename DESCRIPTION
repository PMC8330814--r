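Package: ricecompete
Title: Rice-Weed Competition Modelling Under Elevated Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model rice grain yield under simultaneous weed
    interference and elevated temperature. Implements growing degree day
    (GDD) accounting from daily mean air temperature, the rectangular
    hyperbolic yield-loss model and its combined form in which weed-free
    yield is quadratic in GDD and weed competitiveness is linear in GDD,
    nonlinear least-squares fitting with asymptotic standard errors,
    nested lack-of-fit F-testing for model selection, yield prediction
    surfaces, and a synthetic phytotron-trial generator emulating a
    multi-year temperature-gradient pot experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
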