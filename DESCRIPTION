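Package: DEPore
Title: Dielectrophoresis and Electroporation Dynamics of Blood-Borne Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of the coupled dielectrophoresis (DEP) and
    electroporation response of spherical blood-borne cells (circulating tumor
    cells, white blood cells, platelets). Implements membrane charging, the
    pore nucleation/resealing density equation, optional pore-radius energy
    dynamics, pore-mediated membrane conductivity, Clausius-Mossotti spectra
    with DEP and traveling-wave DEP forces, Stokes-drag trajectory and
    trapping simulation, an axisymmetric conduction solver with a
    contact-impedance membrane interface, and a Cole-type impedance forward
    model of a cell suspension under increasing electroporation voltage,
    mirroring microfluidic impedance-sensing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
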