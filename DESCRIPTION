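Package: ntdsplay
Title: Ensemble Reweighting, Free-Energy and Kinetic Analysis of AMPA
    Receptor N-Terminal Domain Splaying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale analysis pipeline connecting N-terminal domain
    (NTD) splaying of AMPA-type glutamate receptors to desensitization
    kinetics.  Provides "in silico purification" of small-angle neutron
    scattering (SANS) curves contaminated by fractal aggregates,
    Bayesian/maximum-entropy (BME) reweighting of biased conformational
    ensembles against SANS data, a bead-level Debye forward model for
    scattering profiles, weighted histogram analysis (WHAM) of
    umbrella-sampling windows with NTD binding free-energy extraction,
    and exponential fitting of desensitization entry and two-pulse
    recovery currents.  Seeded synthetic-data generators emulate every
    input (two-state tetramer ensembles, contaminated SANS curves,
    umbrella windows, current traces) so the full pipeline is testable
    without molecular-dynamics trajectories or raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
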