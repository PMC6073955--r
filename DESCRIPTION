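Package: dimerdyn
Title: Ensemble Analysis of Homodimer Dynamics and Protomer Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of multi-frame protein coordinate
    ensembles with an emphasis on homodimer asymmetry. Provides multi-model
    PDB input/output, Kabsch least-squares superposition, backbone RMSD in
    fitted and distance-matrix variants, two-dimensional RMSD landscapes,
    per-residue RMSF profiles, geometric hydrogen-bond counting,
    Kabsch-Sander style secondary-structure assignment with beta-strand
    residue counts, Calpha displacement cross-correlation matrices (DCCM),
    single-linkage conformational clustering, and ordinary least-squares
    regression of per-residue correlation differences on fluctuation
    differences between the two protomers of a homodimer. A synthetic
    ensemble generator plants known correlation blocks, fluctuation
    profiles and asymmetry relations so every stage can be validated
    against analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
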