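Package: peptideCS
Title: Chemical-Shift-Driven Conformational Ensemble Analysis for Flexible Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of solution NMR observables for flexible,
    conformationally heterogeneous peptides. Implements random-coil-referenced
    secondary chemical shift analysis and secondary-structure calling, proline
    cis/trans classification from the Cb-Cg shift difference and cis-population
    estimation from peak intensities, combined chemical-shift perturbation
    profiles, amide-proton temperature-coefficient regression, Karplus-based
    3JHNHa back-calculation and validation, per-residue dynamics metrics (Ca
    RMSF, shift-predicted order parameters, T2-filter intensity modelling),
    Kelley-penalty clustering of conformer ensembles, and chemical-shift-RMSD
    driven selection of representative sub-ensembles from candidate multi-model
    PDB ensembles. A synthetic-data generator produces idealized peptide
    ensembles and matching observables with stored ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
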