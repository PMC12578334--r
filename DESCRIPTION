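Package: phtitr
Title: Titration Analysis of Constant-pH Molecular Dynamics Lambda Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of lambda-dynamics constant-pH molecular dynamics
    output into protonation fractions, titration curves and pKa estimates.
    Reads GROMACS-style xvg lambda trajectories, computes threshold and
    lambda-averaged protonation fractions with hierarchical monomer/replica
    averaging, estimates pKa by linear interpolation and by
    Henderson-Hasselbalch and Hill least-squares fits, classifies residues
    with anomalous (censored) ionization, benchmarks pKa prediction methods
    against each other (pairwise RMSD and Pearson correlation with
    censor-aware masking), computes protein net-charge-versus-pH profiles
    with a model-pKa null model, and diagnoses apparent negative
    cooperativity arising from conformational microstate heterogeneity via
    two-component titration mixtures, persistent protonation intervals and
    trace correlation.  Includes a seeded generator of synthetic lambda
    trajectories with prescribed titration behaviour, against whose
    closed-form occupancy every analysis stage is validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
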