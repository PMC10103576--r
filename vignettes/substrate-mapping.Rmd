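---
title: "Simulated substrate electroanatomic mapping in infarcted ventricles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated substrate electroanatomic mapping in infarcted ventricles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eamsim)
```

## The scientific problem

Catheter ablation of ventricular tachycardia (VT) relies on electroanatomic
mapping (EAM): intracardiac electrograms recorded over the chamber surface
during paced or sinus rhythm, from which electrophysiological abnormalities
are inferred. Two functional strategies aim to sharpen that inference:
multiple-wavefront pacing (MWP), which builds several maps by pacing from
different sites so activation crosses the substrate from different
directions, and decremental pacing (DP), which adds an early extra-stimulus
(S2) after the drive stimulus (S1) to stress conduction and expose latent
slowing. `eamsim` provides an in-silico laboratory for these strategies: it
simulates paced rhythms in synthetic infarcted left-ventricular (LV)
models, computes unipolar electrogram maps on endocardial and epicardial
surfaces, extracts six clinically used EAM features, induces re-entrant VT
by programmed stimulation, and quantifies how well single- and multi-map
feature sets identify (i) infarct remodelling and (ii) the critical inner
part of VT circuits.

Because no patient geometries or imaging data are used, every quantitative
claim the package makes is about its own synthetic cohorts, at the level of
directions and signs (e.g. "concordance increases with remodelling
fraction"), not about reproducing any specific clinical correlation value.

## Geometry, coordinates and mapping surfaces

The LV is idealized as a truncated prolate-ellipsoid shell voxelized on a
regular grid (`build_idealized_lv()`; defaults: epicardial semi-axes 34 x
34 x 70 mm, 10 mm wall, 70% apex-to-base truncation, 2 mm voxels). Nodes
carry ventricular coordinates (`assign_uvc()`): apicobasal in [0, 1] from
apex to base plane, rotational in [0, 360) degrees around the long axis,
and transmural in [0, 1] from endo- to epicardium. On this analytic
geometry the coordinates are computed in closed form; they are a
functional stand-in for the Laplace-solve constructions used on irregular
patient meshes, chosen because the package's geometry admits exact
formulas and the coordinates are only used for windows, sectors and
cross-heart standardization.

Fibres follow the standard rule-based construction: the helix angle
interpolates linearly from +60 deg on the endocardium to -60 deg on the
epicardium within the local tangent plane (`assign_fibres()`).

Mapping surfaces (`extract_eam_surfaces()`) are triangulated analytically
at a target edge length of 2 mm, matching the resolution of clinical EAM
geometries. Each side (endo, epi) is a closed genus-0 manifold: the
lateral shell follows the bounding ellipsoid and a flat triangulated lid
closes the base. Lid points exist only for topological closure; they are
flagged and excluded from pacing-site selection, feature extraction and
all analyses, and the nearest-node linkage guarantee (every anatomical
point links to a myocardial node within one voxel diagonal) applies to
anatomical points. Pacing sites are selected per side by farthest-point
sampling under the surface geodesic metric (`select_pacing_sites()`), the
package's concrete reading of "evenly spaced" — the defining property
(each new site is the point farthest from all chosen sites) is asserted in
the tests.

## Synthetic infarct substrate

`generate_infarct()` emulates patchy post-infarct remodelling: seeded foci
at mid-wall depth grown by stochastic dilation on the voxel graph until a
target fraction of the myocardium is remodelled, with acceptance weighted
by the number of already-remodelled neighbours so regions stay compact.
The interior of the remodelled set becomes non-conducting dense core
(rimmed by about two voxels of border zone and capped at 40% of the
remodelled volume); the rest is border zone. `carve_channels()` cuts a
border-zone corridor through the core along a shortest path between two
mouths on roughly opposite sides, guaranteeing a conducting isthmus — the
anatomical prerequisite for re-entry. `generate_cohort()` spreads
remodelling fractions evenly over a configurable range (default 0.10-0.50,
bracketing the reported clinical median of roughly 28.5%) and splits the
cohort at its median fraction into hLIR/hSIR groups.

What the generator does *not* emulate: imaging-derived infarct shapes,
LGE-MRI signal characteristics, inter-patient geometry variation (the
cohort shares one idealized geometry), or papillary/trabecular anatomy.
Passing cohort-level tests therefore demonstrates that the analysis
machinery recovers designed effects under controlled conditions, not that
it reproduces clinical effect sizes.

For pipeline validation there is also a fully deterministic
`engineered_channel_substrate()`: a dense-core sector with a single
border-zone channel whose mouth locations are known by construction, so
the automatic exit-site detector can be validated against ground truth.

## Propagation model

Electrical activity follows the monodomain equation with a two-variable
Mitchell-Schaeffer-type ionic model, integrated explicitly on the voxel
graph (`run_monodomain()`, compiled core). The diffusion operator is a
symmetric graph Laplacian over 6-neighbour edges with per-edge conductance
`n' D n` harmonically averaged between end nodes, where `D = D_t I +
(D_l - D_t) f f'` is built from the fibre direction; no-flux boundaries
are natural and dense core carries no edges. This lattice discretization
ignores cross-derivative anisotropy terms; it is conservative and stable,
and its planar conduction velocity converges under grid refinement (a 4x
refinement changes CV by under 10%, asserted in the tests).

Default parameters (all configurable in `default_sim_config()`):

| parameter | normal | border zone | unit | role |
|---|---|---|---|---|
| tau_in | 0.3 | 0.3 | ms | excitation strength |
| tau_out | 6 | 6 | ms | repolarization |
| tau_open | 70 | 150 | ms | recovery (refractoriness) |
| tau_close | 130 | 170 | ms | action-potential duration |
| v_gate | 0.13 | 0.13 | - | gate threshold |
| D_l | 0.34 | 0.08 | mm^2/ms | longitudinal diffusivity |
| anisotropy | 4:1 | 2:1 | - | conductivity ratio |

These values were calibrated once on slab preparations so that: normal
tissue conducts at about 60 cm/s along fibre with an effective refractory
period between 270 and 290 ms (so an S2 at 310 or 360 ms captures and an
S2 at 150 ms does not); border-zone conduction is roughly half as fast
with a longer refractory period (so decremental stimuli block or slow in
the border zone while capturing normal tissue); and a border-zone isthmus
through scar supports sustained re-entry under programmed stimulation.
The source publications for the study's own tissue parameters are not
reproduced in its text, so these defaults are the package's own, chosen
for the qualitative electrophysiology they produce and documented here.

Stimuli are 2 ms, 2 mm-radius current injections at twice the measured
diastolic threshold. Activation times are threshold crossings of -20 mV
with positive slope, recorded at integration resolution; the potential
field is recorded at 400 Hz (2.5 ms) for electrogram synthesis. The time
step is 0.1 ms, automatically reduced whenever the explicit-Euler
diffusion stability bound requires it.

`deliver_s1s2()` runs the three protocols of the study design (S1 only,
S1+S2 at 360 ms, S1+S2 at 310 ms); capture of each stimulus requires at
least 10% of conducting nodes farther than 10 mm from the site to activate
within the beat window. `induce_vt()` implements programmed stimulation (a
drive train, then S2 scanned downward until block, then S2+S3) from
farthest-point-sampled sites; re-entry is at least two periodic
re-activation cycles at a reference location after pacing ends
(`detect_reentry()`), and episodes are deduplicated by exit-site proximity
(10 mm) and cycle length (10%).

## Unipolar electrograms

The extracellular potential at a surface point x is the
infinite-volume-conductor integral

  phi(x) = -(sigma_i / (4 pi sigma_e)) *
           int grad Vm(y) . (x - y) / |x - y|^3 dV(y),

discretized as a sum over nodes with voxel-volume weights and
central-difference gradients, with source nodes within one voxel of x
excluded (singularity regularization). The map from nodal Vm to point
potentials is linear and geometry-only, so it is assembled once per
geometry (`egm_forward_operator()`) and reused across all time samples,
sites and protocols. Conductivity ratio sigma_i/sigma_e defaults to 0.4.
The kernel reproduces the expected physics, asserted in tests: uniform
fields give identically zero signals, the paced origin shows QS
(negative-dominant) morphology, and amplitudes fall as an inverse-square
dipole field when the distance to a planar front doubles. No torso
boundary or bath is modelled; the unipolar reference is at infinity.

## The six EAM features

Per surface point and per captured beat (`extract_features()`):

- **V_amp** (mV): max minus min of the unipolar signal.
- **CV** (cm/s): per-triangle planar fit of activation time; element CV =
  1/|gradient|; point CV = mean over element centroids within 5 mm.
  Element fits above 200 cm/s are discarded as far-field artefacts.
- **IC** (count, 1-16): sixteen equal time bins between the map's earliest
  and latest activation; crowding = number of distinct bins among points
  within a 1 cm radius. The radius is geodesic along the surface by
  default (Euclidean by flag) — the geodesic reading matches how the
  package measures every other surface distance.
- **FI** (count): deflections in the residual of the signal minus a
  smoothed template. The template is a zero-phase 30 Hz low-pass
  (spectral multiplication by a squared order-4 Butterworth response);
  a deflection is a local-max-to-local-min drop exceeding
  `max(0.05 mV, 4 x median |residual|, 0.2 x largest drop)`. The relative
  term suppresses filter ringing around one dominant deflection. The
  underlying clinical algorithm is not published in reproducible detail;
  this concrete surrogate honours its description (template fit, count of
  significant deflections) and is fully documented and configurable.
- **EGM_dur** (ms): 27.5 ms (11-sample) sliding window, stride one
  sample; duration = time between centres of the first and last windows
  whose SD exceeds 10% of the maximum window SD; 0 for flat signals.
- **FP** (mV^2/ms): area under the one-sided periodogram of the de-meaned
  signal, scaled so that it equals population variance times the sampling
  rate in kHz — Parseval's identity then holds exactly and is asserted to
  1e-9 in the tests.

## Substrate and circuit analyses

A surface point lies over infarct remodelling when at least 10% of
myocardial nodes within 5 mm are remodelled (`project_remodelling()`;
threshold sweepable 0.10-0.50, and raising it is provably monotone).
Pacing sites are ranked by mean geodesic distance to remodelled surface
points (`rank_sites_by_infarct()`).

Concordance between two paced maps is the Pearson correlation of a
feature over points valid in both maps (`feature_concordance()`; Spearman
by flag — the source description says only "correlation", and Pearson is
the common default for continuous map comparisons). Per-heart summaries
average over all unordered map pairs; the package's cohort experiments
then correlate that mean with the remodelling fraction across hearts.

Remodelling detection uses in-sample ridge-penalized logistic regression
over surface points (`fit_remodelling_models()`): the N-th model's
covariates are one feature's values from the N most proximal captured
maps (S2 maps added under the decremental variants), z-scored per map
with mean imputation of invalid points. In-sample evaluation mirrors the
study protocol, which describes no held-out split; the light L2 penalty
(default 1e-3) keeps separable fits finite and is the package's own
implementation choice, as is the z-scoring. Metrics are AUROC (exhaustive
pair counting, ties = 1/2), F1, sensitivity and specificity at a 0.5
probability cutoff (`evaluate_metrics()`), each verified against
brute-force oracles.

VT circuits are analyzed from induced episodes (`analyze_vt_circuit()`):
the exit site is found automatically from boundary "emergence" events
(normal-tissue activations immediately preceded by a border-zone
neighbour's activation, majority-voted across cycles) — replacing the
visual identification used clinically, and validated on the engineered
substrate where the channel mouth is known by construction. The circuit
window spans 0.4 apicobasal units and 72 rotational degrees centred on
the exit (truncated at the apicobasal extremes, wrap-aware
rotationally), the full transmural extent (truncated at the apicobasal extremes); one cycle anchored at the exit
is split into 8 equal isochrones; each in-window surface point receives
the modal isochrone of nodes within 5 mm (ties to the lower index).
Outer circuit = isochrones 1-4, inner = 5-8, per side; VTs lacking a
surface component on a side are flagged and excluded from that side's
analyses. Circuit-component classification pools subregion observations
over VTs (`fit_circuit_models()`), consistent with the per-VT averaging
that precedes the regressions.

## Orchestration, tiers and determinism

`experiment_config()` bundles everything under three resolution tiers:

- **test** — 4 hearts, 12 sites, 2 protocols, 3 mm voxels, 4 mm surface
  edges; minutes of CPU; used for smoke and determinism checks.
- **standard** — 8 hearts spanning remodelling fractions 0.10-0.50,
  8 sites, all 3 protocols (S2 protocols at the 2 most infarct-proximal
  sites), 3 mm voxels; the desk-scale cohort on which the package's own
  sign-level analyses run.
- **full** — the complete 48-heart, 100-site, 3-protocol design
  (14,400 jobs) at 2 mm resolution; hours of CPU, supported by
  configuration but not exercised by the test suite.

`run_experiment()` executes stages in dependency order with per-stage
caching, isolates per-job failures, and derives every random draw from
the master seed, so identical configurations produce byte-identical
result tables and interrupted runs resume to identical outputs.
`enumerate_jobs()` performs the deterministic heart x site x protocol
enumeration (with a dry-run mode). A thin command-line wrapper is
installed at `inst/cli/eamsim.R`.

## Numerical choices and degenerate inputs

- Time step: explicit Euler at dt = 0.1 ms, auto-reduced to 80% of the
  diffusion stability bound; integration aborts with a diagnostic if Vm
  leaves physiological bounds.
- Quiescence early-exit: a simulation ends once the tissue is fully
  repolarized and no stimulus is pending (the recorded trace is padded at
  rest), which makes failed-induction scans cheap without changing any
  recorded quantity.
- Ties: modal-isochrone ties break to the lower isochrone; rank ties
  break by site id; farthest-point-sampling ties break to the lowest
  point index.
- Degenerate inputs: all-equal activation gives IC = 1 and masked CV;
  flat signals give V_amp = FP = EGM_dur = FI = 0; single-class labels
  are errors in the regression ladders; identical groups give p = 1 in
  the comparison helpers; zero-variance maps give NA concordance.

## Limitations

- One idealized geometry serves the whole cohort; anatomical variability
  and its effect on wavefront geometry are absent.
- The two-variable ionic model reproduces conduction, refractoriness and
  restitution qualitatively, not any species- or patient-specific action
  potential; at 3 mm cohort voxels the discrete front slows conduction
  below the fine-grid calibration, which is acceptable for the package's
  sign-level claims.
- The infinite-medium unipolar kernel omits torso and bath boundaries.
- In-sample regression metrics quantify information content of feature
  sets, not out-of-sample predictive performance (a cross-validation flag
  is out of scope here by design).
- Clinical headline numbers from patient-derived cohorts are not
  reproduction targets; only the directions of the reported effects are.
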