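Package: mixopH
Title: Protist Plankton Physiology and Seawater pH in Closed Batch Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates how growth of the five protist plankton functional
    types (phytoplankton, zooplankton, and the generalist non-constitutive,
    plastidic-specialist non-constitutive and constitutive mixoplankton)
    changes dissolved inorganic carbon, total alkalinity and hence [H+]/pH
    in a closed batch system initialised at early-industrial (300 uatm) or
    end-of-century (600 uatm) atmospheric pCO2. Couples a mass-conserving
    quota-based physiology model (phototrophy, phagotrophy with voiding and
    specific dynamic action, internal nutrient recycling, acquired
    phototrophy, leakage) one-way to a seawater carbonate-chemistry solver,
    computes near-cell (proximal) [H+] from diffusion-limited cell-surface
    fluxes, and provides the desk calculations for the balance point
    between phagotrophy and phototrophy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
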