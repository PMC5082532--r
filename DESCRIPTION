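Package: ferromin
Title: Iron-Oxide Co-Precipitation Mass Balance, Ion-Binding Free Energy,
    and Chemical-Shift Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying protein-mediated magnetite nucleation from
    mixed ferrous/ferric solutions. Provides a stoichiometric registry of the
    iron minerals formed during room-temperature co-precipitation, synthetic
    generators and equivalence-point detection for three-plateau pH titration
    curves, lever-rule decomposition of titration end points into mineral
    fractions on the R-versus-X mass-balance diagram, a Metropolis Monte Carlo
    toy simulator of single-ion binding to peptide oxygen sites with radial
    distribution function and Boltzmann-inversion free-energy analysis, and
    chemical-shift perturbation mapping of metal-binding hotspots on the
    C-terminal Mms6 peptide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
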