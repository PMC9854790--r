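Package: oxistab
Title: Oxidative Stability of Seed Oils by EPR Spin Trapping and Chemometrics
Version: 0.1.0
Authors@R:
    person("Analytical", "Pipelines", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the thermal oxidative stability of edible seed
    oils with electron paramagnetic resonance (EPR) spin trapping.
    Simulates isotropic first-derivative spectra of PBN (N-tert-butyl-
    alpha-phenylnitrone) nitroxide adducts from spin-Hamiltonian
    parameters, quantifies spectra by baseline correction, double
    integration and non-negative least-squares decomposition into
    component species, summarizes adduct-intensity kinetics with a
    Boltzmann sigmoid (induction period) and the area under the curve
    (AUC), implements an empirical no-intercept model linking AUC to
    peroxide value, total phenolic concentration and free fatty acids,
    converts raw photometric assay readings (peroxide value, total
    phenolics, DPPH radical scavenging), and runs a total-signal
    normalization / Pareto scaling / PCA data-fusion stage on LC-MS
    style feature tables. A synthetic-data module generates every input
    the pipeline needs, with ground truth, for testing and simulation
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
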