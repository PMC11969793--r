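---
title: "Electrode-rotation planning for tumor-treating-fields therapy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode-rotation planning for tumor-treating-fields therapy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttfplan)
```

## The problem

Tumor-treating fields (TTFields) therapy delivers alternating electric
fields in the 100–300 kHz band through transducer arrays glued to the
skin. Efficacy scales with the field intensity reached inside the
tumor, with a commonly cited therapeutic threshold near 1 V/cm. For an
abdominal target such as a pancreatic tumor, the field that actually
reaches the gross tumor volume (GTV) depends strongly on where the
arrays sit, because abdominal tissue is electrically very
inhomogeneous: bowel gas, bone and fat conduct poorly while stomach
contents, urine and well-perfused organs conduct well, steering current
around or through the target.

`ttfplan` implements a complete in-silico planning loop for the
question "does rotating the standard montage around the tumor improve
the tumor field?": a synthetic segmented abdominal phantom generator, a
surface-conformal electrode-array model, a voxel finite-volume solver
for the quasi-static conduction equation, the standard plan-quality
indices, and a 7-plan rotation-scan protocol that compares one
reference montage against six rotated variants.

## Physical model

At 150 kHz the wavelength and skin depth are both enormous compared to
a human torso, so wave propagation is ignored and the potential obeys
the conduction (quasi-static) equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0, \qquad \mathbf{E} = -\nabla\varphi,$$

inside the body, with zero normal current through the skin except under
the electrodes. Conductivity $\sigma$ is purely real: displacement
currents are neglected. This is the established approximation for
TTFields and transcranial-stimulation dosimetry; permittivity effects
at 150 kHz perturb tissue current magnitudes by far less than the
uncertainty in the conductivity values themselves.

The discretization is cell-centered finite volumes on the voxel grid
with a 7-point stencil. Face conductances use the harmonic mean of the
two adjacent voxel conductivities, which makes the scheme exactly
flux-conservative across tissue interfaces — the property that matters
most when bone (0.02 S/m) sits next to fluid (1.5 S/m). Voxels outside
the body are excluded from the domain, which yields the zero-flux skin
boundary for free.

Electrodes are modeled as equipotential Dirichlet patches (all contact
voxels of an array held at ±1 V), reflecting the fact that the physical
discs are good conductors backed by a common feed. The resulting linear
system is symmetric positive definite and is solved with
Jacobi-preconditioned conjugate gradients to a relative residual of
1e-8 (iteration cap proportional to the unknown count, no randomized
components, so solves are deterministic). Because the problem is
linear, the ±1 V solution is rescaled afterwards so the injected
current matches the prescribed value exactly; injected and extracted
currents are computed independently and agree to well under 0.5%. A
dense direct solver over the same discretization ships in the test
suite as an independent oracle for grids up to 16³.

## Drive settings and electrode geometry

The protocol drives two perpendicular array pairs sequentially —
anterior–posterior (AP) and left–right (LR) — at 150 kHz and a current
density of 31 mA RMS/cm², the clinical abdominal settings. The AP
arrays carry 20 disc electrodes (4×5 grid), the LR arrays 13 (rows of
4-5-4), matching the clinical array models. The vendor publishes only
the electrode counts and the output limit, so disc size is a modeling
choice here: the default disc radius (8.52 mm) is fixed so that the
20-disc array area equals 1414/31 ≈ 45.6 cm², reproducing the device's
printed maximum output of 1414 mA RMS at 31 mA RMS/cm². Disc radius,
spacing and layout are all configurable in `electrode_layout()`. The
per-pair target current is the current density times the analytic
contact area of the array (so the 13-disc pair draws 13/20 of the AP
current); the clinical output limit is interpreted per active pair.

Arrays are placed relative to the tumor centroid: each disc is the
endpoint of a ray cast from the (laterally offset) centroid to the body
surface, so arrays conform to the skin the way physical arrays do.
Rotation for a trial plan is applied rigidly to the whole montage —
direction rays and in-plane bases of all four arrays rotate together
about the tumor centroid, preserving the perpendicularity of the two
pairs — and discs are re-projected onto the surface afterwards.
Positive angles are clockwise in the standard radiological views: the
axial plane is viewed from inferior, the sagittal plane from the
patient's left. (The convention only becomes observable on asymmetric
anatomy; the protocol scans ± both angles regardless.) A surface voxel
claimed by two discs is assigned to the nearer disc center; since all
discs of an array are equipotential, this choice affects bookkeeping
but not the physics.

No gel/interface layer is modeled by default: contact is applied
directly on skin voxels. A contact layer would add a roughly uniform
series resistance per array and, under current-controlled drive, has
little effect on the interior field distribution.

## The two sequential orientations

The device energizes the AP and LR pairs alternately, not
simultaneously. How the two per-orientation field maps should be
collapsed into one per-plan value is not standardized; `ttfplan`
defaults to the duty-weighted mean of the two magnitude maps with
weights (0.5, 0.5) — the time-average field experienced by each voxel —
and also offers a per-voxel `max` rule. All metrics are computed from
the combined map, whichever rule is configured.

## Plan-quality indices

With $E_p$ the prescribed field — defined as the **reference plan's
mean GTV field**, fixed once per phantom and reused for every trial
plan — the package reports, per plan:

* $E_{min}, E_{mean}, E_{max}$: exact voxel statistics over the GTV
  (the minimum is the true minimum, not a percentile);
* homogeneity index $HI = (E_{max} - E_{min}) / E_p$ (lower is more
  uniform);
* coverage index $CI = V_{100,GTV} / V_{GTV}$, the GTV volume fraction
  at or above $E_p$ (inclusive threshold, "at least 100%");
* DVH curves: volume fraction at or above each normalized field level,
  1%-of-$E_p$ bins from 0 to 200%. By construction the curve starts at
  1, never increases, and its 100% bin equals the CI exactly.

The best trial plan is chosen per index over the six trials only
(argmin for HI, argmax otherwise). Ties break toward the plan closest
to the reference geometry: smallest |angle|, then axial before
sagittal, then positive before negative. Improvements are reported as
percentages of the reference value, with the HI sign flipped so that
positive always means better; plans are additionally reported
normalized to the reference plan (trial/reference ratios).

## The synthetic phantom generator

No patient imaging ships with the package, so the phantom module
generates segmented abdomens: an ellipsoidal body of background muscle
(semi-axes 150 × 105 × 170 mm by default), a posterior spine column of
cortical bone, liver on the right, stomach and spleen on the left,
paired posterior kidneys, a central pancreas, and a spherical GTV
(22 mm default radius, ~45 mL) near the body center — a deliberate
subset of a full abdominal segmentation, enough to create realistic
field inhomogeneity around a pancreatic target. Organs are painted in
list order (later wins), the GTV last. Conductivities at 150 kHz are
shipped as an editable table assembled from published human-tissue
dielectric compilations (muscle 0.43, cortical bone 0.021, liver 0.12,
kidney 0.27, stomach 0.54, pancreas 0.52, tumor 0.30, free fluid
1.5 S/m, ...); they are configuration, not ground truth.

Two controls emulate a patient population: seeded Gaussian jitter of
organ centers (inter-patient variability; 6 mm SD in the cohort
scripts) and a lateral shift of the high-conductivity stomach/spleen
(25 mm in the cohort scripts) that breaks left-right symmetry. The
generator is fully deterministic given its spec, including the seed.

What the phantoms do **not** capture: realistic organ shapes, fat
layers, bowel gas, peristalsis-scale heterogeneity, and patient-specific
conductivity. Passing tests therefore demonstrate that the pipeline's
physics, indices and protocol logic are correct and that the
direction-of-effect (rotated montages can beat the reference on
asymmetric anatomy) is reproduced — not that any specific clinical
improvement percentage transfers to real patients.

Two phantom specs are shipped as text fixtures. The *asymmetric*
fixture places a large high-conductivity fluid pocket anterior-left of
the tumor and a bone column posterior-right, so the straight AP/LR
montage loses current around the tumor while oblique montages drive it
through — the geometry on which the rotation scan demonstrably helps.
The *symmetric* fixture is exactly mirror-symmetric about the
mid-sagittal plane and is used as a null control: +θ and −θ axial plans
must agree to solver tolerance. Its x-dimension is odd on purpose: with
a voxel-center column on the symmetry plane, half-voxel rounding ties
mirror exactly and the montage voxelization is bitwise symmetric.

## Numerical choices and edge cases

* World coordinates are mm; axes are left→right (x), posterior→anterior
  (y), inferior→superior (z); a voxel's world position is its center;
  generated phantoms are world-centered on the body.
* Field magnitudes use central differences in the interior and
  one-sided differences where a neighbor is outside the body; exterior
  voxels report 0. Fields are reported in V/cm, currents in mA RMS.
* CG tolerance 1e-8 (relative residual) keeps field differences of
  interest (≥0.1%) far above solver noise; the iteration cap scales
  with the unknown count and non-convergence is an error, never a
  silent result.
* Degenerate inputs fail loudly: empty GTV, tumors outside the body,
  electrodes on non-conducting voxels, disconnected source/sink,
  missing conductivity entries (reported by label), non-integer or 4-D
  label volumes.
* Problem sizes: the shipped fixtures are 64³ (5 mm voxels) and 49³
  (6.5 mm); the cohort scripts use 48³ (6.7 mm) with 13 phantoms. These
  resolve the organ geometry and keep a full 7-plan scan (14 solves) in
  the tens of seconds on one CPU; the discretization itself is
  resolution-agnostic.

## Workflow

The `analysis/` scripts chain the pieces: `01_simulate_phantoms.R`
writes the 13 cohort phantom specs, `02_run_protocol_scans.R` runs the
7-plan scan on each and stores per-plan metrics,
`03_summarize_cohort.R` builds the per-phantom improvement table and
the cohort-mean summary, and `04_fixture_dvh.R` produces the worked
single-case example with DVH curves. `run_bundle()` packages the same
loop as a single self-describing output bundle whose echoed
`run_config.yaml` reproduces `metrics.csv` byte-identically, and
`scripts/acceptance.R` recomputes the headline quantities (slab solver
error, fixture scan, cohort summary) from scratch.

```{r example, eval = FALSE}
spec <- read_phantom_spec(system.file(
  "extdata", "synthetic_asymmetric_phantom.yaml", package = "ttfplan"))
scan <- run_protocol_scan(generate_phantom(spec))
print(scan)
```

## Known limitations

* Ellipsoidal organ geometry and spherical tumors only; no real-CT
  intensity simulation or auto-segmentation.
* Purely real conductivity; no permittivity, no Joule heating.
* The montage search space is the fixed 7-plan rotation protocol; no
  continuous placement optimization or array translation.
* Per-index best-plan selection (a plan can win on CI and lose on HI);
  no composite objective and no statistical testing across phantoms.
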