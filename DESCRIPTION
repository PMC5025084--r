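Package: hepzone
Title: Zonated Sinusoid Model of Hepatic Glucose, Lipid and Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compartmental kinetic simulator of glucose, lipid and energy
    metabolism along the liver sinusoid. The porto-central axis is split into
    well-mixed hepatocyte/blood compartments in series with plug-flow blood
    advection, a systemic body compartment (pancreatic hormone secretion,
    adipose tissue, gut and muscle), zonated Hill-type rate laws for every
    hepatic process, and a fixed periportal-to-pericentral oxygen gradient.
    Disease scenarios cover insulin resistance, SREBP-1c over-expression and
    diet variation for the study of non-alcoholic fatty liver disease
    (NAFLD), together with local sensitivity analyses of rate and zonation
    constants, deterministic calibration of unprinted parameters, and
    conservation/refinement verification audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
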