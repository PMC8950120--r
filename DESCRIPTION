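Package: maxentfes
Title: Maximum-Entropy Reweighting of Metadynamics Ensembles for Protein
    Unfolding Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates free-energy changes along a collective variable from
    biased ("metastatistics") molecular ensembles. Implements coordination-number
    collective variables with a rational switching function, gaussian-sum
    metadynamics bias bookkeeping with altruistic multiple-walker mixing and
    quartic smoothing, maximal-constrained-entropy modulation of the ensemble
    (Lagrange-multiplier solving, cross-entropy, block and propagated errors),
    MM/PBSA-style mean-field solvation (numeric solvent-accessible surface area
    and a finite-difference linearized Poisson-Boltzmann solver), Kabsch
    superposition and related structural observables, and a desk-scale
    multiple-walker Langevin toy sampler for end-to-end validation of the
    reweighting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
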