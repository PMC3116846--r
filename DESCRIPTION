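Package: circadapt
Title: Light Adaptation and Entrainment Analysis for a Minimal Circadian Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a three-variable circadian oscillator
    (Hill-type negative feedback on transcription) under light-dark forcing with
    transient ("adaptation"), slow-response and square light-induction waveforms.
    Provides a fixed-step Runge-Kutta integrator aligned to forcing
    discontinuities, stroboscopic Poincare-map machinery (entrained-orbit
    location by Newton iteration, monodromy matrices and Floquet multipliers,
    saddle-node/period-doubling/Neimark-Sacker bifurcation location, attractor
    classification), phase response curve (PRC/PTC) computation with analytic
    entrainment and stability criteria, reconstruction of the time-varying
    transcription rate from sparse mRNA and total-protein time series, and a
    ground-truthed synthetic-data generator emulating published sampling
    designs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
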