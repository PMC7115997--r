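Package: aquaflux
Title: Single-File Water Transport Through Membrane Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and inverse fitting procedures for quantifying
    osmotic water transport through narrow membrane channels such as
    aquaporins, gramicidin derivatives and the potassium channel KcsA.
    Implements the classical single-file (Finkelstein) relations between
    unitary permeability, pore length and intraluminal water mobility; the
    Lambert-W closed form and ODE forward models of osmotic vesicle
    deflation together with monoexponential and full-curve fitting routines
    that extract the membrane osmotic permeability Pf from stopped-flow
    light-scattering traces; steady-state unstirred-layer concentration
    profile analysis for scanning-microelectrode experiments; channel-census
    conversions (electrical counting, two-step FCS particle counting, and
    permeability-versus-density slope methods) that turn ensemble Pf into
    unitary pf; log-linear structure-function regressions of pf on the
    single-file water count N or the hydrogen-bond residue count N_H; and
    the transition-state-theory link between pf and the Gibbs activation
    barrier, including Arrhenius analysis of temperature series. Seeded
    synthetic-data generators emulate every supported experiment so the
    fitters can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
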