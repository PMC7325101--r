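Package: cvdpimex
Title: Cardiovascular and Diabetes Burden of Physical Inactivity in Mexico
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) simulation of coronary heart
    disease, stroke and type-2-diabetes dynamics in the Mexican adult
    population, stratified by physical-inactivity status. Provides a
    synthetic-input generator emulating the national data sources the model
    requires, iterative rate calibration to event and death targets,
    counterfactual physical-inactivity scenario comparison (including WHO
    2025/2030 relative-reduction trajectories), and Monte Carlo propagation
    of relative-risk and prevalence uncertainty. Packaged fixtures transcribe
    the published ENSANUT physical-inactivity prevalence table and the
    7-year projected case counts so that all reporting arithmetic is
    reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
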