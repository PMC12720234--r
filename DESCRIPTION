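Package: modescan
Title: Normal-Mode Potential-Energy-Scan Analysis of Ground and Excited States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing one-dimensional potential energy scans of
    molecular electronic states along Cartesian vibrational normal modes.
    Generates displaced geometries from an equilibrium structure and a set of
    normal-mode vectors, assembles per-mode per-state energy scans from
    tabulated single-point energies, fits each scan with a quadratic and
    reports curvature, horizontal-shift and goodness-of-fit statistics,
    detects excited-state crossings along a scan and relabels states
    diabatically, quantifies per-mode anharmonicity (normalized fit RMSD) and
    Franck-Condon activity (per-mode relaxation energy), categorizes modes by
    a simplified potential-energy-distribution projection onto internal
    coordinates, and classifies every mode into one of eight cases combining
    anharmonicity and Franck-Condon flags. A synthetic two-state generator
    with controllable Morse anharmonicity, minimum displacement and state
    crossings replaces the quantum-chemistry engine for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
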