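Package: seqlandscape
Title: Latent Generative Landscapes and Domain-Motion Analysis for Transporter Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generative design and evaluation of P-type ATPase
    transporter sequences. Curates protein family alignments (length,
    gap-run and identity filters), infers a mean-field direct coupling
    analysis (DCA) Potts model with Hamiltonian and Direct Information
    scoring, trains a two-dimensional variational autoencoder on one-hot
    encoded sequences, and combines both into a latent generative
    landscape (LGL): a regular latent grid where every pixel is a decoded
    sequence annotated with its Potts Hamiltonian. Candidate sequences
    decoded from the landscape are screened for novelty, conserved motifs
    and per-domain mutation load. A companion trajectory toolkit
    quantifies actuator-domain motion in molecular dynamics trajectories
    (tilt angle, displacement toward the E1 state, a percent movement
    score) and transmembrane helix rearrangement via distance difference
    matrices, with unit-root stationarity checks. Seeded synthetic-data
    generators (Gibbs-sampled Potts families, subgroup mixtures, and
    two-state toy trajectories with known ground truth) support
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
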