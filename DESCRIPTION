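Package: acidscale
Title: Self-Consistent Acidity Scales in Low-Permittivity Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing self-consistent Bronsted acidity scales in
    low-permittivity media such as 1,2-difluorobenzene. Turns UV-vis spectra of
    jointly titrated acid pairs into dissociation degrees and relative ion-pair
    acidities by linear spectral unmixing, converts ion-pair acidity differences
    into pKa differences with Fuoss ion-pair dissociation corrections, assembles
    pairwise difference measurements into an anchored least-squares ladder with a
    consistency statistic and outlier-series exclusion, processes differential
    potentiometry traces into quality-controlled unified-acidity (pH_abs)
    differences, fits cross-solvent pKa transfer regressions with uncertainty
    assignment rules, and converts solvent-scale pKa values to the unified
    aqueous-referenced acidity scale via proton solvation Gibbs energies.
    Seeded synthetic-data generators emulate every measurement type so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
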