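Package: petalvision
Title: Ozone Effects on Flower Visual-Attraction Traits via Spectral
    Reflectance and Pollinator Colour Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying ozone effects on the visual attraction
    traits of flower petals. Reads and preprocesses petal reflectance
    spectra, computes the anthocyanin reflectance index (ARI) and spectral
    peak metrics, maps spectra into bee (colour hexagon), fly (categorical)
    and butterfly (tetrahedral) colour spaces from photoreceptor quantum
    catches with von Kries adaptation, classifies perceptible colour
    differences, and implements the associated statistics: PERMANOVA on
    Bray-Curtis dissimilarities of transformed spectra, planned a-priori
    contrasts in one-way ANOVA/ANCOVA, and random-intercept model selection
    by AIC. Includes ozone-exposure metrics (AOT40, daylight-window means,
    open-top-chamber microclimate comparisons) and a synthetic-data
    generator for anthocyanin-type petal spectra, petal areas and hourly
    ozone series so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
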