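---
title: "Probabilistic coverage of intracranial electrodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic coverage of intracranial electrodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegcover)
```

## The scientific question

Whether penetrating depth (SEEG) leads or subdural strip and grid arrays
record from more brain tissue is a long-standing question in epilepsy
surgery planning. `ieegcover` models a contact's recording reach as a
*radius of influence* (RoI): a sphere around the contact centroid within
which tissue counts as covered. Because no single radius is valid for all
signal types, coverage is swept across radii (1–15 mm in 0.5 mm steps by
default) and summarized per implant class (`S`, `S+G`, `S+G+D`, `D`).

Three modeling ingredients matter:

1. **Probability-weighted volumes.** Tissue segmentations are
   probabilistic: each voxel carries probabilities of being gray matter,
   white matter, or CSF. Coverage is the sum over covered voxels of
   `p(tissue) * voxel volume`, so partial-volume voxels contribute
   fractionally. Subcortical nuclei and cerebellar gray are excluded from
   gray/white totals, since they are rarely intended recording targets.
2. **Union, not sum.** A patient's covered volume is the union of all
   contact spheres: tissue seen by several contacts counts once. This is
   what makes inter-contact spacing matter — 5 mm-spaced depth contacts
   overlap heavily beyond a 2.5 mm RoI (redundancy), while 10 mm-spaced
   subdural contacts keep accruing fresh tissue.
3. **Brain-shift correction.** Subdural contacts localized from
   postoperative imaging can sit up to a centimetre inside the
   preoperative brain surface. Before computing coverage they are
   projected back onto a smoothed gray-matter surface (binary mask at a
   probability threshold, morphological closing with a 24 mm spherical
   kernel to bridge sulci, marching-tetrahedra level set). Interhemispheric
   contacts have their sampling restricted to the hemisphere they record
   from.

## The synthetic phantom: what it emulates, and what it does not

Real patient imaging cannot ship with a package, so every stage runs on a
generated phantom "brain": a white-matter core under a gray-matter ribbon
of fixed cortical thickness whose top surface undulates sinusoidally
(gyri and sulci), topped by CSF, split into two hemispheres by a
CSF-filled fissure, with deep gray blocks (hippocampus, amygdala,
subcortical nuclei, cerebellar gray) embedded in the white matter.
Partial volume at interfaces is a logistic function of the signed
distance to the interface (width `softness_mm`), mimicking the soft
boundaries a probabilistic segmentation produces without implementing
one.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| extent | 100 × 100 × 80 mm | one hemisphere pair at roughly life size |
| voxel size | 2 mm (1 mm in small tests) | keeps a full cohort run in seconds |
| cortical thickness | 3 mm | human neocortex averages ~2.5–3 mm |
| gyral wavelength / amplitude | 20 / 6 mm | sulci ~10 mm wide and ~12 mm deep, enough that a 24 mm closing kernel bridges them |
| CSF layer | 6 mm | separates the smoothed surface from the skullless boundary |
| fissure gap | 4 mm | typical interhemispheric width |
| partial-volume softness | 1 mm | sub-voxel interface blur |
| depth / subdural spacing | 5 / 10 mm | the clinical lead geometries being compared |
| contact geometry | disc ⌀2.3 mm; cylinder 2.29 × ⌀0.86 mm | standard subdural and SEEG contact dimensions |

The cohort generator places subdural strips and 5 × 8 grids on the
gyral-crown plane (where the smoothed surface runs, so half the contacts
float over bridged sulci), and three kinds of depth trajectory: leads
targeting the hippocampus or amygdala, near-tangential mediolateral leads
that traverse the cortical ribbon (as SEEG trajectories are planned to
maximize traversed gray matter), and deep vertical leads that run into
central white matter. Observed electrode tables carry a configurable
inward brain shift on subdural contacts; the pre-shift truth is kept for
validation. Layout anchors are jittered patient-to-patient under a fixed
seed.

What the phantom does **not** emulate: real gyral geometry and its
curvature statistics, registration and segmentation error, CT localization
artifacts, vasculature-driven trajectory constraints, or cohort-scale
anatomical variability. Passing tests therefore demonstrate that the
*pipeline* implements its stated model faithfully and that the *mechanism*
(spacing-driven redundancy plus sulcal burial) produces the expected
qualitative contrasts — not that the package reproduces any particular
clinical cohort's numbers.

## Numerical choices

- **Voxel membership** is by voxel-center distance, with no anti-aliasing:
  the probability maps already encode partial volume. A consequence worth
  knowing: a single voxelized sphere at r = 2.5 mm on a 1 mm grid can
  deviate from 4/3·π·r³ by ±15% depending on where the center falls
  between voxel centers; the *expectation* over sub-voxel placements is
  exact, which is how the geometric test oracles are phrased.
- **One distance field per patient.** The whole radius sweep uses a single
  distance-to-nearest-contact field (with separate fields for
  hemisphere-restricted interhemispheric contacts), so the 29-radius sweep
  costs one pass over the volume plus 29 thresholded sums, and
  monotonicity in radius holds by construction.
- **Morphological closing** is computed from two exact Euclidean distance
  transforms (anisotropic Felzenszwalb) with internal padding so the
  closing is not clipped at the array border; the "24 mm kernel" is the
  structuring-element *diameter*. A geometric caveat: a ball of radius
  12 mm sags ≈1.1 mm into a 10 mm slit, so bridged sulci retain a shallow
  meniscus at their mouth.
- **Surface extraction** runs marching tetrahedra (conforming Kuhn
  subdivision, watertight by construction) on the signed distance field of
  the closed mask at level 0, which traces the geometric mask boundary
  midway between voxel centers.
- **Projection direction**: the normal of a principal-axes plane fit to
  the contact and its nearest same-lead neighbors (≤4 for grids, 2 for
  strips); collinear neighborhoods (strips) and isolated contacts fall
  back to nearest-point projection. Both satisfy the planar and spherical
  analytic cases. Contacts farther than 25 mm from the surface are flagged
  and left unprojected with a warning.
- **Hemisphere splitting** at the midsagittal plane with hole filling; the
  0.1 mm mean-filter kernel default is smaller than any voxel and is
  documented as effectively the identity (it is configurable because the
  value is plausibly a typo in its original description). Contacts exactly
  on the plane go to a configurable tie-break side (left by default) with
  a message. White matter is restricted alongside gray for
  interhemispheric contacts; a flag disables that.
- **Crossover detection** reports the smallest swept radius where the
  sign of the mean per-contact difference between two classes flips
  relative to a reference radius. The cohort pipeline anchors the
  reference at the smallest named radius (2.5 mm) because radii below the
  phantom's 2 mm voxel size produce order-of-one-voxel coverage whose sign
  is quantization noise.

## The finite-element stage

To test whether spheres are a reasonable stand-in for physical recording
volumes, the package solves the quasi-static conduction equation
∇·(σ∇V) = 0 on a tetrahedral mesh of the phantom head (CSF 1.79, gray
0.33, white 0.142 S/m; lengths in mm, conductivities converted to S/mm so
voltages are in volts) at 1 mA injected current. Choices:

- **Mesh**: a structured node lattice (default edge 1.5 mm, chosen so a
  full single-contact solve stays well under a minute on one CPU) with
  six-tetrahedra Kuhn cells, each element labeled by the majority tissue
  at its centroid; background elements are dropped so the mesh boundary
  is the outer CSF envelope.
- **Source**: the injected current is distributed with hat weights over
  the nodes inside the contact's geometric footprint, never less than
  about one lattice edge. A spherically symmetric source leaves the
  exterior field of a monopole unchanged (shell theorem) while removing
  the anisotropic near-field a single-node point load exhibits on this
  lattice — without it, iso-potential volumes at small radii are visibly
  lumpy.
- **Ground**: Dirichlet V = 0 on the top 5% of the outer boundary by
  facet-area quantile along +z, mimicking vertex screws. For validation
  against the infinite-medium solution V = I/(4πσr), the solver instead
  imposes the analytic potential on the entire outer boundary ("ground at
  infinity"); with a desk-scale domain the top-ground configuration alone
  perturbs the field at 10 mm by more than the 10% comparison band.
- **FEM recording volume**: threshold at the mean of |V| over 500
  Fibonacci-sphere samples at the nominal radius (|V| rather than signed
  V, and sampled rather than integrated — both configurable), then keep
  voxels whose interpolated |V| reaches the threshold. In a homogeneous
  medium this reproduces the sphere (Dice ≥ 0.95 at 1.5 mm edges); a
  conductive CSF layer next to a surface contact elongates the volume
  along the CSF and lowers the Dice, the geometry-driven effect the stage
  exists to expose.

Current conservation holds discretely (ground reaction equals −I to
solver precision), the solution is linear in I, and one uniform
refinement moves probe potentials by under 5%.

## Statistics

Group comparisons use the Kruskal–Wallis rank test (tie-corrected,
chi-squared approximation) on per-patient coverage, all pairwise implant
classes at the named radii, Bonferroni-corrected over the pair count —
the correction family is the per-radius, per-tissue panel. Dispersion is
reported as median ± IQR, consistent with the nonparametric tests. A
fully degenerate input (all values identical) is defined to return H = 0,
p = 1. Dice distributions are compared by Pearson chi-squared on pooled
decile bins (expected counts ≥ 5 per cell after pooling); the binning is
one defensible reading of an ambiguous description, so a Kruskal–Wallis
alternative is available via `method = "kruskal"`.

## Problem sizes used in tests

The shipped test-suite and acceptance script run: geometric oracles on
≤40³ voxel grids with ~200 random sphere placements; an 8-patient cohort
(2 per implant class) on the 2 mm, 100 × 100 × 80 mm phantom with FEM
off; and FEM validation on a 40 mm gray-matter cube at 1.5 mm mesh edges
(~18k nodes). These sizes were chosen as the smallest at which each
property is cleanly resolved; all scale up through the same interfaces.

## Known limitations

- The RoI model is binary in/out; signal amplitude decay inside the
  radius is deliberately out of scope.
- The phantom's sinusoidal folding is one-dimensional; real sulcal
  geometry buries relatively more gray matter, so absolute coverage
  numbers are not transferable to patients.
- The FEM head model has CSF/gray/white only (no skull or scalp), uses
  isotropic frequency-independent conductivities, and monopolar sources.
- Projection assumes the smoothed surface is the correct target for every
  subdural contact; heavily displaced contacts (>25 mm) are flagged
  rather than guessed at.
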