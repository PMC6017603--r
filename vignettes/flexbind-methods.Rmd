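---
title: "flexbind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flexbind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexbind)
```

flexbind relates the conformational ensemble of a flexible protein
domain to its equilibrium small-molecule binding. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices made where the methods literature is
silent, and what the synthetic-data tests do and do not demonstrate.

## 1. Ensemble geometry

**Superposition and RMSD.** All comparisons between conformations use
least-squares rigid superposition (Kabsch algorithm via the SVD of the
3×3 cross-covariance). Reflections are excluded by forcing
`det(R) = +1`, so a mirror image is never matched onto its original.
Selections of fewer than three atoms, or (near-)collinear selections
(second singular value below 1e-8 of the first), are rejected as
degenerate: the rotation is not determined by them. The test suite
checks the optimum against an independent Euler-angle grid search
(coarse 3° scan of all of SO(3), local refinement to 0.5°, translations
handled in closed form by centroid matching).

**RMSF.** Per-residue fluctuation is computed after superposing every
frame onto the ensemble-average structure; the average is then
recomputed and the superposition repeated once (two passes), since the
mean structure is itself defined by the superposition. Backbone means
N, CA, C, O. Atom-level fluctuations are averaged within each residue.
Because the rigid-body fit absorbs six degrees of freedom, RMSF is
biased low by roughly `sqrt(1 - 6/(3·n_atoms))`; with the ≥ 40-residue
ensembles used in the tests this is well under 1%, inside the 2%
tolerance applied to the `σ√3` recovery law for isotropic per-coordinate
noise of amplitude σ.

**Solvent-accessible surface area.** Shrake–Rupley quadrature with
1200 points per atom and a 1.4 Å water probe by default. The point set
is a deterministic golden-spiral (Fibonacci) lattice rather than a
random sampling, so areas are bit-reproducible across platforms and
runs. Radii default to a Bondi-like set (C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20, P 1.80 Å) and are fully configurable; an element
without a radius is an error naming the element, never a silent
default. Two-sphere configurations are verified against the analytic
spherical-cap area to 2% — roughly the discretisation error of a
1200-point lattice.

**Hydrophobic-surface series.** The per-frame sum of SASA over
hydrophobic residues (default class ALA, VAL, LEU, ILE, PRO, PHE, MET,
TRP; configurable) inside a region of interest. The region is a
*required* argument: a hydrophobic-patch analysis on a whole protein
mixes unrelated surface, and sensible patch scales (tens of Å²) only
arise locally. Occlusion is always computed against the full
structure; only the summation is restricted. The maximal frame is the
argmax with ties broken towards the lowest frame index, so the
selection is deterministic.

**Clustering.** The conformational clustering is the leader (GROMOS)
algorithm on pairwise superposed-RMSD: the frame with the most
neighbours within the cutoff (default 2.0 Å, backbone selection)
becomes a centroid; it and its neighbours are removed; repeat. This is
the standard construction behind "frames grouped within a distance
cutoff" phrasing in the MD literature, and it guarantees every member
lies within the cutoff of its centroid. All ties (neighbour counts,
equal occupancies) break towards the lowest frame index, making the
partition deterministic given frame order. The pairwise matrix is
computed from pre-centred selections; for ensembles beyond a few
thousand frames it should be preceded by `subsample_frames()`, which is
how the package expects 10⁴–10⁶-frame trajectories to be handled.

## 2. Binding propensity (inverse-docking aggregation)

The propensity statistic asks: across the ensemble, in what fraction of
frames could the ligand bind the way it binds in a reference complex?

* **Pose distance.** Each frame is superposed onto the reference frame
  using the *pocket backbone* atoms, the transform is applied to the
  pose, and the ligand heavy-atom RMSD to the reference pose is taken
  with no ligand re-fitting. This metric counts both translation and
  orientation errors while being immune to global tumbling of the
  protein. The pocket-local fit was chosen over a global fit so that
  breathing of distal regions does not contaminate the measurement.
* **"Able to bind".** A frame is bound iff its best (lowest-score) pose
  lies within a distance cutoff (default 2.0 Å) of the reference pose
  *and* scores at or below a threshold; a natural threshold is the
  reference pose's score + 1 kcal/mol. Propensity is then
  `n_bound / n_frames`, monotone in both cutoffs by construction. The
  joint criterion mirrors the usual workflow of grouping poses by
  distance and then comparing group mean energies; distance alone
  would count clashed poses, score alone would count poses in the
  wrong sub-pocket.
* **Reference pose.** Taken as an input (a structure or pose file),
  normally the representative pose of the most populated cluster of a
  ligand-complex trajectory. Simulating that complex is outside this
  package's scope, which is why the reference is an input and not a
  derived quantity.
* **Pose provenance.** The built-in `toy_dock()` engine is a
  deterministic rigid-body grid/orientation search with a transparent
  score (soft-sphere clash penalty, distance-weighted contact reward,
  geometric H-bond bonus; all coefficients in `dock_params()`). It is
  intentionally simple enough that its optimum can be recomputed by
  brute force in the tests, and it is pluggable: externally produced
  poses enter through `read_pose_file()` (multi-model PDB with
  `REMARK SCORE` / `REMARK FRAME` records, scores formatted to six
  decimals so round-trips are exact). The score is not a physical
  binding free energy and is never interpreted as one.
* **Contacts.** H-bonds use the donor–acceptor heavy-atom distance
  (≤ 3.5 Å) plus a ≥ 120° donor angle when explicit hydrogens are
  present; with no hydrogens the distance criterion alone applies and
  the angle is reported `NA`. N, O and S are treated as H-bond-capable,
  since thioether/thiazole sulphurs participate in the binding modes
  this analysis targets. π–π stacking is flagged on aromatic
  ring-centroid distance ≤ 5.5 Å, with protein rings from residue
  templates (PHE/TYR/TRP/HIS) and ligand rings perceived as planar 5-
  or 6-cycles of a 1.8 Å distance-bond graph.
* **Pose groups.** Best poses are histogrammed into fixed-width
  distance bins (default 2 Å, configurable): bin `k` covers
  `[k·w, (k+1)·w)`, and each group reports its size, mean score and
  mean distance.

## 3. Steady-state SPR

* **Model.** One-site Langmuir: `Req = Bmax·C/(Kd + C)`. Kinetic
  (ka/kd) fitting is deliberately not implemented: the analysis targets
  steady-state titrations; the kinetic 1:1 model exists only inside the
  sensorgram generator.
* **Equilibrium extraction.** Mean response over the final 10% of the
  injection window (configurable), with a linear-slope check: if the
  fitted drift across the window exceeds 2% of the window mean the
  estimate is flagged non-plateau rather than rejected — degraded data
  should be visible, not silently dropped.
* **Fitting.** Nonlinear least squares (Levenberg–Marquardt,
  `minpack.lm::nlsLM`, parameters bounded below by 0) initialised from
  the Scatchard linearisation `Req/C = Bmax/Kd − Req/Kd`. The
  linearisation is used *only* for starting values: fitting it directly
  is known to bias Kd because it distorts the error structure. When the
  Scatchard regression is degenerate (non-negative slope), a curve-free
  heuristic start (`Bmax = 2·max(Req)`, `Kd = median(C)`) is used; on
  well-conditioned isotherms both starts converge to the same optimum
  (checked to 1e-9 relative RSS in the tests).
* **Saturability.** The design is saturable when the top concentration
  reaches at least 2·Kd (configurable factor); otherwise the Kd is
  reported with `presumed = TRUE`, the flag used for compounds whose
  solubility caps the titration below saturation.
* **Surface density.** 1 RU = 1 pg/mm², the standard
  carboxymethyl-dextran chip convention; density in fmol/mm² follows by
  dividing by the molar mass. The package's worked example (7800 RU of
  a 53.5 kDa protein → ~146 fmol/mm²) is consistent with this
  convention.
* **Competition.** `percent_change = 100·(Req_mix − Req_alone)/Req_alone`;
  negative values are inhibition, positive enhancement. The sign
  convention is stated in the result object rather than folded into a
  magnitude, because the same assay reports both competitors and
  co-binders.

## 4. Correlation and reporting

With a ligand panel of typical size n = 4–8, asymptotic correlation
p-values are invalid. `correlate()` therefore computes Pearson *and*
Spearman statistics (the underlying association is not assumed linear)
with one-sided permutation p-values by full enumeration of all n!
pairings when n ≤ 8, and seeded Monte-Carlo (add-one estimator) above
that. At n = 4 the smallest achievable one-sided p is 1/24 ≈ 0.0417,
and the result object states this floor explicitly so small-panel
significance is never over-read. Exact p-values are deterministic and
invariant to input order; Spearman results are invariant under
monotone transforms of either variable.

In the report, a ligand's "maximal binding" is the fitted `Bmax` when
the titration saturated, else the highest observed equilibrium response
(flagged through `Kd_presumed`); non-binders and ligands missing from a
block are listed separately (`non_binders`, `unmatched`) and excluded
from the correlation, never silently dropped.

The pipeline's stage-by-stage surface is realised as the exported R
functions plus the umbrella `run_pipeline()`; this is an analysis
library for R sessions and scripts, not a shell tool, so no separate
command-line wrapper is shipped.

## 5. The synthetic-data generators

Every generator returns a ground-truth record sufficient to test the
stage that consumes its output; all randomness is Mersenne–Twister
under a caller-supplied seed, and changing the seed changes noise
realisations but never the planted parameters.

* **Trajectory.** An idealised α-helical backbone (rise 1.5 Å/residue,
  100°/residue, atoms N, CA, C, O, CB) plus i.i.d. Gaussian per-atom
  displacements scaled by per-residue σ, so the expected RMSF is
  exactly `σ√3`. Two-state pocket dynamics: each frame is open with
  Bernoulli probability `open_fraction`, and open frames shift the
  pocket-lining residues (default: the last quarter of the chain) by a
  displacement vector. Because a rigid fit absorbs part of any subset
  displacement, the generator can rescale the vector by fixed-point
  iteration so the *superposed* backbone RMSD between closed and open
  templates equals a requested `target_separation` — the planted
  between-state distance is then exact, not approximate. The default
  study conditions are a 24-residue helix, σ = 0.3 Å, 200 frames at
  200 ps, 30% open, 5 Å separation, clustered at a 2 Å cutoff.
* **Pose sets.** Bernoulli(`bound_fraction`) per frame; bound poses
  jitter around the reference pose (per-coordinate Gaussian chosen so
  the expected RMSD is `bound_noise` ≈ 0.3 Å) with scores strictly
  below the threshold; unbound poses are displaced by at least
  `unbound_offset` (6 Å) with scores strictly above it. The bound set
  is therefore recoverable exactly, and the propensity estimator
  returns the realised binomial fraction; its deviation from the
  planted fraction is pure binomial sampling error, `sd = √(f(1−f)/n)`.
* **Sensorgrams.** Closed-form 1:1 Langmuir association
  `R(t) = Req(1 − e^{−(kon·C + koff)t})`, exponential dissociation,
  additive Gaussian noise and optional linear drift; the generator
  satisfies detailed balance `kon·C·(Rmax − Req) = koff·Req` at
  equilibrium to 1e-9 relative. Default design: concentrations
  `Kd·{0.25, 0.5, 1, 2, 4, 8}`, 90 s injections, 1% of Rmax noise —
  the panel's Kd values (24.2, 40.3, 99.3, 197.9 µM) span the
  magnitudes such titrations typically probe.
* **Competition.** Paired fast-equilibrating traces whose plateaus
  implement a signed percent effect (+94% and −50% are the panel's
  bookends, alongside +29% and 0%).

**What the generators do not emulate.** Atomic noise is i.i.d. — there
are no correlated collective motions, no solvent, no force field; the
helix template is idealised geometry, not a refined structure; the
docking score is a toy; SPR traces lack bulk-shift steps, spikes,
mass-transport limitation and DMSO solvent artifacts. Passing the
recovery tests therefore demonstrates that the *estimators* are
correct and well-calibrated on data satisfying their assumptions — it
does not validate the pipeline against real MD ensembles or real
sensorgrams, whose systematic errors are outside this model class.

## 6. Problem sizes and numerical tolerances

The test suite exercises the study-scale conditions at sizes chosen to
keep the full run in minutes on one core while leaving the statistical
targets sharp: RMSF recovery at 5,000–10,000 frames (2% tolerance on
`σ√3`, rank correlation > 0.95 on 30 prescribed amplitudes), clustering
recovery on 20 independent 150-frame two-state ensembles, propensity
recovery on 100 replicates × 1,000 frames per planted fraction, Kd
recovery on 100 noisy isotherms (median |error| < 10%), a 3°→0.5°
rotation grid oracle on 50 five-atom cases (agreement to 1e-3 Å), and
the full pipeline at 200 trajectory frames / 1,000 pose frames per
ligand. Equality tolerances follow the format or algorithm: 1e-3 Å for
PDB round-trips (three-decimal coordinates), six-decimal exactness for
pose scores, 1e-8 for rotation orthonormality, 1e-9 relative for RSS
and detailed-balance identities.

## 7. Known limitations

* The leader clustering is O(n²) in frames; very long trajectories
  must be subsampled first (the intended workflow).
* SASA is computed in pure R with neighbour pruning; hundreds of frames
  × hundreds of atoms is routine, but whole-protein trajectories at
  every frame are better subsampled.
* Contact annotation uses heavy-atom geometry and residue templates; it
  does not protonate structures, perceive tautomers, or distinguish
  donor from acceptor chemistry beyond element type.
* The toy docking engine ranks placements for testing and plumbing; it
  is not a substitute for a physical scoring function and its energies
  have no thermodynamic meaning.
* `ru_to_density()` assumes the dextran-chip mass-response constant;
  other surface chemistries need a different conversion factor.
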