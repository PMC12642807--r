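Package: symbiovade
Title: Consumer-Resource Dynamics of Microbially-Mediated Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the coupled population dynamics of native and
    invasive hosts together with their microbial symbiont communities,
    using a consumer-resource formulation in which the benefits and
    costs of symbiosis arise from explicit, density-dependent resource
    fluxes. Host-symbiont associations fall on a continuum from
    parasitism to mutualism, classified by the signed net-interaction
    coefficients Q_p and Q_m. Provides the four-compartment and reduced
    two-compartment model equations, stiff-capable numerical
    integration, equilibrium location with linear stability analysis,
    invasion experiments with asymptotic outcome classification and
    extinction-pathway tracing, regime-region maps in exchange-rate
    space, outcome phase diagrams, constrained parameter sampling, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
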