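Package: ischsim
Title: In Silico ECG Detection of Early Myocardial Ischemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-beat electrocardiograms of early (10-minute)
    left-ventricular ischemia on a parametric voxelized biventricular model
    and evaluates ST-deviation features across body-surface lead systems.
    Ventricular excitation is computed with a first-arrival cellular
    automaton under ischemia-reduced conduction velocity, transmembrane
    voltage courses follow phenomenological action-potential templates
    modulated by a per-voxel zone factor, and body-surface potentials are
    obtained from an equivalent current-dipole forward model. Implements
    the ST-segment deviation (STSD) and K point deviation (KPD) features,
    detection-rate statistics over threshold grids, subgroup reports by
    ischemia radius, border-zone size, transmurality, subject and AHA
    segment, and optimization of a single additional precordial electrode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
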