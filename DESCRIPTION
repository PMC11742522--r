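Package: masldsim
Title: Microsimulation of the Natural History and Burden of MASLD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Agent-based annual-cycle state-transition model of metabolic
    dysfunction-associated steatotic liver disease (MASLD) in a dynamic
    US-like population, 2000 to 2050. Couples a demographic component
    (initial age and sex structure, births, net migration, life-table
    mortality) with parallel MASL/MASH fibrosis tracks, decompensated
    cirrhosis, hepatocellular carcinoma, liver transplant, and
    liver-related mortality. Includes calibration of free parameters to
    published prevalence and registry anchors, a deterministic
    expectation oracle for validation, and scenario and one-way
    sensitivity analyses of projected disease burden.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
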