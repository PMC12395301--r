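---
title: "Methods: latent generative landscapes and domain-motion metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent generative landscapes and domain-motion metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic validation does and does not
demonstrate about real data. Nothing quantitative is stated here that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The design pipeline

### 1.1 Alignment curation

The input is a family alignment over the fixed alphabet
`ACDEFGHIKLMNPQRSTVWY-` (gap last; the ordering is frozen so one-hot
encodings are reproducible). Curation applies three filters:

* **Length** (`length_filter`): keep records whose ungapped residue count
  lies in an inclusive window. For the P1B-type transporter family the
  window 574–661 residues selects single-pump architectures; the bounds
  are arguments, not constants.
* **Gap runs** (`gap_run_filter`, default `max_run = 25`): drop any record
  containing more than 25 consecutive gaps. Long gap runs are usually
  alignment artifacts of fragments or distant architectures; the filter is
  idempotent.
* **Identity subsampling** (`identity_subsample`, default 0.87): greedy
  scan in input order, keeping a record iff its identity to every
  previously kept record is below the threshold. Greedy-in-order is
  deterministic and order-stable; a seeded shuffle is available when the
  input ordering itself is a nuisance variable. Pairwise identity is
  defined as matches at mutually non-gap columns divided by the shorter
  ungapped length — one definition used consistently by the subsampler,
  the DCA reweighting and the novelty check. The phrase "subsampling below
  87% identity" admits a second reading (sampling a subset of low-identity
  pairs); the redundancy-reduction reading implemented here is the
  standard one in alignment curation.

A2M input treats lowercase letters and `.` as insert states and removes
them per record (profile-HMM convention), so the aligned length equals the
number of match columns.

### 1.2 Mean-field DCA

Sequences are reweighted (`compute_weights`, threshold 0.8): each record's
weight is the reciprocal of its neighborhood size at ≥80% identity, and
Meff is the weight sum. Frequencies (`empirical_frequencies`) carry a
pseudocount λ mixed as `λ/q + (1−λ)·counts/Meff` (pairs: `λ/q²`). The
defaults λ = 0.5 and 0.8 are the canonical mean-field DCA settings for
protein alignments; neither is sacred, and both are exposed. Couplings
are the negative inverse of the connected-correlation matrix on the
reduced alphabet (gap as reference state); fields follow self-consistently
from the single-site frequencies. A singular correlation matrix (e.g.
λ = 0 with duplicated columns) raises an error that names the remedy
(increase λ).

Two caveats the tests make explicit:

* The pseudocount itself perturbs the connected correlations (the
  smoothed pair table is not the product of smoothed marginals), so
  "couplings vanish on independent sites" holds only as λ → 0 and
  n → ∞. The test asserts smallness at λ = 0.01, n = 20,000 and decrease
  with n.
* Mean-field inversion is a truncation: on enumerable models (L = 3,
  q = 2) the inferred model's exact pairwise marginals match the
  generating ones to within 0.02 at weak coupling, which is the regime
  where the approximation is honest.

**Scoring.** `hamiltonian` is Eq-faithful: −Σ h − Σ e, gap symbols
contributing through their learned parameters with no special casing; a
gauge shift of any position moves every score by the same constant, so
rankings are gauge-invariant. `sequence_probability` normalizes by full
enumeration and is guarded to q^L ≤ 10⁶ states. **Direct Information** is
the mutual information of the two-site distribution induced by
`exp(e_ij)` with auxiliary fields fitted so its marginals match the
empirical single-site frequencies (fixed-point iteration, tolerance 1e-6,
cap 500 iterations — convergence failure is an error naming the pair, not
a silent fallback).

### 1.3 The VAE

Architecture: one-hot input of width L·q → one ReLU hidden layer of 3·L
units → (μ, log σ²) of a 2-D Gaussian posterior; decoder mirrors it
(2 → 3·L ReLU → L·q logits, per-position softmax). The 3·L width is read
as *one* hidden layer per network; "3·L total across layers" is the other
reading and was rejected as the less literal one. The ELBO is the
categorical reconstruction log-likelihood minus the closed-form KL to the
standard-normal prior.

Training: Adam, learning rate 1e-4, L2 penalty 1e-4 applied to the weight
matrices (not biases — the penalty is described as acting on the hidden
units, and biasing the offsets serves no regularization purpose), batch
size 64 (unstated upstream; 64 is a conventional default), hard cap
`max_epochs = 1000`. The per-epoch loss is the mean minibatch loss of the
epoch; training stops when it has failed to improve on the running best
for `patience = 10` consecutive epochs. There is no validation split:
the stopping loss is the training loss, matching a setting where the
curated family *is* the corpus. All randomness (initialization, shuffling,
latent noise) flows from one seed, so training logs and parameters are
bit-reproducible on a machine.

Determinism conventions: `vae_encode` returns the posterior *mean* (one
fixed point per sequence — maps are reproducible, no sampling);
`vae_decode` takes the per-position argmax with ties broken toward the
lowest alphabet index (one deterministic sequence per latent point).

### 1.4 The landscape

`build_grid` spans the bounding box of the training encodings expanded by
10% per side (encodings must be interior; the margin is an argument), with
500 points per axis by default — 250,000 pixels. Pixels are ordered
row-major with z₀ fastest. `score_map` decodes every pixel and scores it
with the Potts Hamiltonian, in chunks of 25,000 pixels to bound memory;
the map is a pure function of (VAE, Potts model, grid).
`decode_candidates` returns the *cached* sequence of the nearest pixel
(Euclidean, ties to the lower pixel index) so that candidates quoted from
a stored map are exactly reproducible; decoding 250,000 pixels once and
caching was chosen over re-decoding per analysis.

Candidate screening: `novelty_check` (exact max identity to the family),
`motif_check` (plain-string motifs located in the gap-stripped sequence,
1-based ungapped positions), `mutation_report` (per-domain substitution
and indel counts over 1-based inclusive column ranges, which must not
overlap; uncovered columns are tallied as "other").

A landscape-geometry caveat: with the low learning rate and early
stopping above, the decoder can remain close to a per-position consensus
over much of the latent plane, and because ReLU networks extrapolate
linearly, far-from-data pixels decode to *amplified* consensus sequences
that a Potts model may score slightly better than near-data pixels. The
property "pixels near the training encodings score better than far
corners" is therefore asserted with a better-converged decoder (learning
rate 1e-3); with the default rate the contrast is not reliable. Users who
read fitness off the far field of a landscape should check decoder
convergence first.

## 2. Trajectory analysis

All metrics are computed in the frame of the E2Pi transmembrane helices:
each trajectory frame, and the E1 reference, is rigid-body superposed onto
the E2Pi reference over the 8-helix selection (least-squares fit via
bio3d). The first 50 ns are excluded as equilibration
(`equilibration_trim`; frames with t ≤ trim are dropped).

* **Tilt angle**: the angle between v₁, the vector along the MB′ helix
  kink (between the centers of mass of two kink groups), and v₂, from the
  basal-helix anchor to the center of mass of the A-domain β-sheets.
  Computed as `atan2(‖v₁×v₂‖, v₁·v₂)` in degrees — the numerically robust
  form with range [0°, 180°]; a cross product alone does not define an
  angle. Which basal helix anchors v₂ is a selection-config choice, not
  hard-coded.
* **Δdistance**: Euclidean distance between the A-domain center of mass
  in the frame and in the (aligned) E1 reference, in Å.
* **Movement score**: with F = (θ, Δd) and reference vectors measured
  from the two reference structures (never hard-coded),
  `(1 − ‖E1−F‖/‖E1−E2Pi‖)·100`. Identical reference vectors are an error
  (zero target distance). The score mixes degrees and Å deliberately —
  it is a progress coordinate, not a metric — and is therefore invariant
  under isotropic rescaling of both axes but not anisotropic rescaling;
  the tests assert both directions to guard unit handling.
* **DDM**: entry (a,b) is the change in center-of-mass distance between
  helices a and b from reference to frame, *absolute* by default (the
  summaries of interest — maxima and block contrasts — are sign-agnostic;
  a signed variant sits behind `signed = TRUE`). Centers of mass are
  unweighted over the selected atoms; with real structures the
  conventional selection is Cα-only, left to the selection config.
  Interblock summaries contrast the 4×4 (MA,MB,M1,M2) × (M3–M6) submatrix
  with the intrablock triangles; the per-trial "coupled" value reported by
  `run_traj` is the interblock maximum at the frame of maximum progress.
* **Stationarity**: an augmented Dickey–Fuller regression with constant
  (lag order ⌊(n−1)^{1/3}⌋ by default), p-values interpolated from the
  standard finite-sample quantile table of the τ_μ statistic; stationary
  ⇔ p < 0.05. A constant series is reported stationary with a
  `degenerate` flag rather than erroring. The test is implemented in the
  package because no installed package provides one; its calibration
  (≥90/100 seeded white-noise series stationary, ≥90/100 random walks
  not) is asserted in the suite.

## 3. Synthetic data: what it emulates, what it does not

`make_planted_potts` / `sample_potts` generate families from a known
Potts model by single-chain Gibbs sampling (burn-in 1000 sweeps, thinning
10 by default — verified against exact enumeration at L = 3, q = 2, where
sampled pair frequencies match to < 0.02 at n = 20,000). Planted pairs use
"matching" couplings e(a,a) = 2 with Gaussian fields (sd 0.3): a strong,
clean covariation signal. `make_family_mixture` adds subgroup structure by
giving each subgroup a field bonus (+2) for a preferred symbol at half the
positions — enough separation that intra-subgroup identity exceeds
inter-subgroup identity, emulating the clustering that real families show
in latent space.

`make_two_state_trajectory` builds a toy pump: a static two-row scaffold
of 8 ten-atom helices, static kink and anchor groups, and a rigid 60-atom
A-domain that travels from its E2Pi to its E1 placement as t goes 0 → 1.
The domain's center of mass follows an in-plane path whose direction angle
is linear in t and whose distance to the E1 position equals (1−t)·travel —
the radius along the path solves the law of cosines — so the frame's
(θ, Δd) vector traverses the straight segment between the reference
vectors and the noise-free movement score equals 100·t *exactly*. Defaults
(θ: 60° → 40°, travel 12 Å, anchor radius 20 Å, 400 frames over 400 ns,
noise σ = 0.5 Å per coordinate) were chosen once as a plausible scale for
an actuator-domain transition and are not tuned thereafter. Optional
block-2 displacement translates the (M3–M6) helices along x by t·shift;
helix pairs are laid out collinear with that axis so the maximum
interblock DDM equals the planted shift exactly. Noise is added *after*
placement, so ground truth always refers to noise-free geometry, and the
references stay noise-free.

What passing these tests shows: the estimators are correct on data whose
generating process matches their assumptions, at the stated sizes
(families of L = 30, n = 500–2000; trajectories of 400 frames). What they
do not show: robustness to phylogenetic correlation (Gibbs samples are
exchangeable; real families are not — reweighting mitigates but does not
remove this), to alignment error, to non-rigid domains, to correlated MD
noise, or to reference structures that are themselves imperfect. The
acceptance-style checks are correctness checks, not benchmarks of
biological accuracy.

## 4. Orchestration

`run_design` and `run_traj` execute the two chains from a single strictly
validated config (YAML file or list): unknown keys anywhere are rejected,
thresholds are range-checked, and failures are classed as config errors
vs stage errors with the failing stage named. Every run writes its
artifacts (curated FASTA, encodings/DI/map TSVs, candidate FASTA, motion
and DDM tables) plus a manifest containing an MD5 hash of the scientific
config (the output location is excluded) and digests of every artifact;
identical configs and seeds reproduce identical manifests. Model and map
persistence uses plain-text formats (TSV/FASTA/JSON) throughout — the
containers are small and text survives every toolchain.

Problem sizes used throughout the suite (chosen as the smallest sizes at
which the statistical assertions are stable): mixture families of L = 30,
n = 500; planted-recovery families of n = 2000 across 5 seeds;
enumeration oracles at L = 3, q = 2 with n = 20,000 samples; one
full-resolution 500 × 500 landscape; 400-frame trajectories.

## 5. Known limitations

* Mean-field DCA is an approximation; pseudolikelihood or Boltzmann
  machine variants are out of scope, as is contact benchmarking against
  structures.
* The VAE trains on CPU with full-batch shuffled minibatches; GPU
  training, alternative priors and annealing are out of scope.
* The Hamiltonian color scale of a rendered landscape is left to the
  user; raw scores are exported.
* `sequence_probability` is exact and therefore refuses models beyond
  10⁶ states rather than silently approximating.
* The trajectory toolkit reads reference structures from PDB and
  trajectories from multi-model PDB, plain XYZ or in-memory objects;
  binary MD formats (DCD/XTC) are not parsed here — convert upstream.
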