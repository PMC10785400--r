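---
title: "Consensus blind docking on a voxel grid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus blind docking on a voxel grid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Blind docking asks where on a protein's surface a small molecule binds,
with no prior knowledge of the site. Individual docking programs answer
with scored pose sets; cavity detectors answer with ranked pockets.
Each component is noisy on its own, but where several independently
concentrate output is strong evidence of the true site. `voxdock`
operationalises that consensus:

1. A cubic lattice of 10 Å voxels is drawn over the protein's padded
   bounding box, and every predicted pose and pocket is assigned to its
   containing voxel.
2. Each occupied voxel becomes a feature vector: per docking program
   $P$, the pose count `sampled_pose_number_P_at_location`, the
   distance from the voxel center to the nearest assigned pose
   mass-centre (`P_distance`), and the best program-native score
   (`P_best_score`); per cavity tool $T$, the best assigned pocket rank
   (`T_min_pose_id`), the analogous `T_distance`, and the tool's
   descriptor columns. Empty voxels are removed.
3. A feature-selected, class-weighted stacked classifier maps each
   voxel to a binding-site probability in $[0, 1]$.
4. The top-scoring voxel is mapped back to the nearest detected cavity
   (joint union of both tools); that cavity centroid is the predicted
   site, around which a 15 Å local-docking box plan is emitted.

Supervision comes from co-crystallised complexes: the voxel containing
the crystal ligand's heavy-atom mass centroid is the one positive
example per target; every other retained voxel is negative. Missing
features (a failed program, an absent score, an untouched voxel) are
mean-imputed with training-set column means.

The assumptions worth stating: a binding site is compact at the 10 Å
scale, so one voxel captures it; program agreement is informative even
when no single program's top pose is right; and score scales never need
to be harmonised across programs, only given a polarity (energy-like
scores are minimised — vina, plants, galaxydock — while zdock's is
maximised).

## Feature selection

Feature selection is the Boruta shadow procedure, implemented here
directly: every iteration appends a column-shuffled shadow copy of each
still-undecided feature, fits a class-weighted random forest
(`ranger`, impurity importance), and credits a feature with a *hit*
when it out-scores the best shadow. Hits are tested against
Binomial(trials, 1/2), two-sided at `alpha` (default 0.05): consistent
winners are confirmed, consistent losers rejected, and anything still
undecided after `max_iterations` (default 100) stays tentative
(dropped by default, keepable by flag). No multiple-testing correction
is applied across features — the canonical algorithm's behaviour. The
procedure is deterministic given its seed.

One-way ANOVA F-scores (`stats::oneway.test`, equal-variance form) are
reported alongside for interpretability, with two conventions for
degenerate inputs: an everywhere-constant feature scores 0, and a
feature with between-group separation but zero within-group variance
reports a capped sentinel (`1e12`) rather than `Inf`.

## The voxel scorer

The classifier is an explicit, seedable bagging + multi-layer stacking
procedure. Layer 1 fits each base learner — gradient-boosted trees
(`xgboost`), random forest (`ranger`), and a ridge-penalised logistic
model (`glmnet`) — bagged over stratified bootstrap resamples (5 bags
by default, resampling within class so every bag sees the rare
positives). Out-of-fold predictions, with folds drawn at *target*
granularity so no voxel of a held-out target ever leaks into a training
fold, are appended to the features of the next layer (2 layers by
default). A logistic meta-learner on the final layer's out-of-fold
predictions yields the calibrated probability; no separate calibration
stage is needed. Class imbalance (one positive per target against
dozens of negatives) is handled by balanced class weights in every
learner; nothing is resampled away.

The 80/20 split between training and validation is likewise at target
granularity, and a dedup hook (`dedup_by_similarity()`) accepts
externally computed structural-similarity scores (e.g. TM-scores) and
removes training targets strictly above 0.5 similarity to any held-out
target; a score of exactly 0.5 is kept.

## Numerical choices

* **Voxel assignment** is containing-box under floor indexing with
  half-open intervals $[lo, hi)$; a point exactly on a boundary belongs
  to the higher box. Points outside the grid (far-flung decoy poses)
  clamp to the nearest boundary voxel, which preserves the partition
  property (every pose counted exactly once).
* **Padding** defaults to 5 Å so surface-adjacent poses stay in
  bounds; **resolution** defaults to 10 Å.
* **Ranking tie-breaks** are content-based and deterministic: equal
  voxel scores break by greater total pose count, then lexicographic
  voxel index; equal cavity distances break by smaller cavity rank,
  then fpocket before p2rank. Results therefore never depend on input
  ordering.
* **Labels**: the positive is the single centroid-containing box, even
  for ligands spanning several boxes; if that box was filtered as
  empty it is re-inserted with missing (then imputed) features so the
  positive survives.
* **Thresholds are strict**: a site hit is distance $< 8$ Å, a pose hit
  is RMSD $< 2$ Å; both are configurable.
* **Centroids** are mass-weighted over heavy atoms (standard atomic
  masses), with a geometric option; hydrogens are excluded throughout
  because docking outputs and the RMSD metric are heavy-atom based.
* **Protonation is out of scope**: `clean_target()` strips waters,
  monoatomic ions, free atoms and bound ligands but assigns no
  hydrogens; emitted docking plans note that inputs are expected
  pre-protonated.

## Evaluation metrics

Site identification is scored by the Euclidean distance between the
predicted site centroid and the crystal ligand's mass centroid, with
accuracy at the standard 8 Å threshold plus mean and median distances.
Pose prediction uses the heavy-atom RMSD

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}
  \left[(x_i - x_{i,\mathrm{ref}})^2 + (y_i - y_{i,\mathrm{ref}})^2 +
        (z_i - z_{i,\mathrm{ref}})^2\right]}$$

without superposition (both poses already live in the receptor frame).
The symmetry-corrected variant minimises this over all automorphisms of
the element- and bond-order-labelled molecular graph, enumerated by VF2
search (`igraph`) with vertex colours for elements and edge colours for
bond orders, so chemically equivalent relabelings (ring flips, rotated
ring numbering) cannot inflate the error. Connectivity comes from
SDF/MOL2 bonds when present and otherwise from distance-based
perception (covalent radii + 0.45 Å, flagged as perceived). Ligands
whose automorphism count exceeds a cap (default $10^6$) skip the search
and return the identity-correspondence RMSD, flagged.

One subtlety: the inequality *symmetric ≤ plain* holds whenever the
identity atom pairing is itself admissible, i.e. pred and ref share a
consistent numbering — the usual docking situation. If the prediction
arrives arbitrarily relabelled, the plain RMSD's file-order pairing is
chemically meaningless and can be numerically smaller than the best
graph-respecting pairing; the symmetry-corrected value is the
defensible one. The test suite checks equality against a brute-force
permutation oracle on relabelled poses and the inequality on
matched-numbering poses.

Benchmark summaries report per-dataset accuracy/mean/median plus an
*unweighted* cross-dataset average row (each dataset counts equally,
matching the usual "Average" panel presentation); the alternative
pair-weighted average was considered and rejected as conflating dataset
sizes with method quality.

## The synthetic scenario generator

Every stage is testable offline against generated targets. One target
comprises: a carbon pseudo-atom cloud, uniformly filling a sphere
(default radius 25 Å) and thinned to ≥ 3 Å spacing; one true site and
`n_decoy_sites` decoys (default 4) on the surface, pairwise ≥ 12 Å
apart so 8 Å hits are unambiguous; per-program pose sets in which each
pose lands at the true site with probability `program_accuracy`
(0.6 easy, 0.3 hard) and otherwise at a random decoy, Gaussian-spread
with `pose_spread_sigma` (2.5 Å); program-native scores drawn so
true-site poses are better by `score_separation` (2.0 score units) in
each program's polarity; cavity lists for both tools as the sites
perturbed by `cavity_noise_sigma` (2 Å), the true site taking rank 1
with probability `cavity_true_rank_bias` (0.5), with plausibly biased
descriptors; a rigid 8-heavy-atom crystal ligand placed at the true
site; and whole-program failures at `program_failure_rate` (0.02,
matching the low observed failure rates of real blind-docking runs;
pose counts default to vina 9, plants 10, galaxydock 20, zdock 100,
echoing ZDOCK's characteristically large output). Everything is
deterministic given `(seed, index)`.

What the generator deliberately does **not** emulate: real protein
topology and chemistry, conformational strain, correlated errors
between programs (each program's poses are drawn independently), or
each program's true score scale. Passing tests therefore demonstrate
that the pipeline's machinery — featurization, selection, stacking,
mapping, metrics — is correct and recovers planted signal; they do not
certify accuracy numbers on real benchmark complexes, which require
executing the external programs.

## Problem sizes used by the test suite

The packaged checks train on 60 generated targets and evaluate on 20
held-out targets (easy setting), a size at which site recovery is
expected above 90 % while a feature-shuffled control falls to the
decoy-rate baseline; difficulty monotonicity is checked at
program-accuracy 0.6/0.45/0.3 with 20 evaluation targets each, sharing
per-target RNG streams so the accuracy knob is monotonically coupled;
Boruta behaviour is checked over 100 seeded planted-signal runs at
n = 400 and 30 pure-noise runs. Monte-Carlo checks of the scorer use
24–40 targets per condition, chosen so sampling noise stays well inside
the asserted margins.

## Known limitations

* Real-program adapters (fpocket directories, P2Rank CSV, Vina PDBQT,
  generic multi-entry molecule files) are best-effort conveniences over
  unstable native dialects; the versioned JSON interchange format is
  the tested contract.
* ZDOCK's native transformation output is not decoded; its poses must
  arrive as coordinate files.
* Local docking is planned, not executed: the package emits a 15 Å box
  plan with the fallback order (plants, then vina, then galaxydock) and
  consumes whatever poses the user's external run produced.
* Alternate locations beyond 'A', NMR models beyond the first, and
  hydrogen placement are out of scope for structure handling.
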