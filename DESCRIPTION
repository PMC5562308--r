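Package: cuaging
Title: Semi-Mechanistic Modelling of Copper Aging in Soils
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the decline in lability (isotopic exchangeability) of
    water-soluble copper added to soils as a function of incubation time,
    soil pH, organic carbon content and temperature, using a semi-mechanistic
    model that combines precipitation/nucleation, occlusion within organic
    matter, and micropore diffusion described by the complementary error
    function with Arrhenius temperature coupling. Includes isotope-dilution
    E-value computation, constrained nonlinear least-squares parameter
    estimation with long-horizon trend anchors, a synthetic-data and
    parameter-recovery harness, a 20-soil field validation dataset, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    optparse,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
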