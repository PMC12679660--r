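Package: cortigen
Title: Neural-Field Simulation and Self-Organization of Cortical Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates delay-coupled neural fields with three-timescale
    Hebbian and anti-Hebbian synaptic plasticity, and quantifies the
    emergence of zero-lag synchronous oscillation through spatial
    eigenmode analysis, variational free energy of synaptic flux,
    prediction-error residuals and channel capacity.  A morphogenesis
    stage grows columnar and mirror-symmetric cell layouts by force
    equilibrium between synchrony maximization and wiring-length
    minimization, and a complex angle-doubling projection synthesizes
    orientation-preference maps with pinwheel singularities, linear
    zones and saddle points, together with twelve-point representation
    frames for rigid moving images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
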