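---
title: "Modelling and validating direct electrocortical stimulation voltages on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and validating direct electrocortical stimulation voltages on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Direct electrocortical stimulation (DECS) delivers current through subdural
ECoG contacts resting on the cortical surface. Patient-specific
finite-element models predict the voltages this generates in the brain, but
two localization parameters dominate their accuracy: where the contacts
actually sit after post-implantation *brain shift* (the brain moves relative
to pre-operative imaging, by millimetres to centimetres), and how much
cerebrospinal fluid (CSF) lies between a contact's underside and the
cortex. `ecogvolt` implements the full modelling-and-validation chain for
this problem — electrode localization under brain shift, volume-conduction
simulation, quasi-static voltage extraction from recorded pulse trains, and
the comparison statistics — and, because patient imaging and intracranial
recordings cannot be redistributed, exercises every stage on synthetic
phantoms whose ground truth is known by construction.

## The forward model

The quasi-static potential $V_e$ obeys the Poisson equation
$\nabla \cdot \sigma \nabla V_e = -i$ in the head volume $\Omega_C$, with
insulating (pure-Neumann) conditions $\partial_\Gamma V_e = 0$ on the outer
boundary and a bipolar source $i = I_0(\delta_{x_+} - \delta_{x_-})$ at the
stimulating contact pair. Compartments carry isotropic literature
conductivities (S/m): gray matter 0.330, white matter 0.142, CSF and
ventricles 1.790, and the silicone carrier sheet $10^{-10}$. Working in
millimetres with currents in mA and $\sigma$ in S/m yields potentials
directly in volts.

Discretisation is linear (P1) tetrahedral finite elements. The stiffness
operator is assembled element-wise from barycentric gradients; it is
symmetric with zero row sums, so the pure-Neumann problem is singular up to
an additive constant. The solver is conjugate gradient with a Jacobi
(diagonal) preconditioner to a relative residual of $10^{-8}$, with
iterates deflated against the constant null space; the gauge is fixed to a
zero-mean solution. A compatible load ($\sum_k b_k = 0$) is enforced at
construction: the stimulus current is spread over each contact's 73 disk
nodes through their P1 interpolation weights, whose rows are normalised to
sum to exactly one. Spreading the source over the disk (rather than a
single-node delta) keeps the sampled self-voltage mesh-independent; a
single-node mode remains available for the analytic verification, which
compares the solver against the image-charge half-space solution
$V(x) = \frac{I}{2\pi\sigma}\left(\frac{1}{r_+} - \frac{1}{r_-}\right)$.

### Meshing

No tetrahedral mesh generator is available to the package at run time, and
meshing is not the scientific contribution here, so `tetrahedralize()` uses
a structured tensor-product construction: grid planes are placed exactly on
the phantom's layer interfaces (gray top, CSF film, sheet top and bottom,
and any clipping plane), each grid cell is split into six tetrahedra
sharing the cell's main diagonal (Kuhn subdivision, which is conforming
across cells), and every tetrahedron is labelled by classifying its
centroid against the compartment surfaces innermost-first. Cells outside
all compartments are dropped; the insulating outer boundary is then simply
the mesh boundary. In-plane resolution is graded geometrically from
`h_fine` (default 2.5 mm) under the electrode footprint to `h_coarse` far
away. Electrode disks (2.3 mm diameter, 73 nodes: centre plus rings of 12,
24 and 36 at radii $r/3$, $2r/3$, $r$) are embedded by locating each disk
node in its containing tetrahedron and storing barycentric weights; those
weight rows both inject current and sample the simulated electrode voltage
(mean over the 73 nodes). The 73-node count is the modelled contact
discretisation; its ring layout is this package's choice of a near-uniform
arrangement. Because disk nodes are embedded by interpolation rather than
forced to be mesh vertices, electrode "node sets" are supports of the
interpolation weights; region volumes and the solved fields are insensitive
to this choice at the validated tolerances.

Verification against the half-space oracle on a $240 \times 240 \times
80$ mm slab (1 mA pair 10 mm apart, samples 5–30 mm away) gives a maximum
relative error of about 8.6% at 5 mm resolution, falling monotonically to
about 3.1% at 1.25 mm (roughly 27k nodes, seconds of runtime); reciprocity
holds to ~$10^{-12}$ and amplitude linearity to round-off. These problem
sizes are the package's desk-scale defaults; clinical-resolution meshes
(~0.9 M nodes) follow the same construction but are not what the tests run.

## Electrode localization

Post-implant ("rigid") contact centroids come from the mean of the CT metal
artifact's thresholded voxel cloud. Three projection methods return them to
the *closed gray matter surface* (the gray surface after morphological
closing, so contacts land on gyral crowns rather than inside sulci):

* **Principal axis** — each contact independently travels along the
  dominant eigenvector of its artifact covariance to the first surface
  intersection. The eigenvalue dominance ratio must exceed 1.2, otherwise
  the axis is declared degenerate and the contact is reported by name.
* **Hermes** — a total-least-squares plane is fitted to the contact and its
  lattice neighbours (4-neighbourhood; corners borrow one diagonal so the
  fit always has at least four points; strips combine their 1–2 neighbours'
  tangent with the local surface normal), and the contact is projected
  along the plane normal.
* **Dykstra** — constrained minimisation of
  $E = \sum_i \lVert e_i - e_{i0}\rVert^2 + \sum_{i<j} a_{ij}(d_{ij} -
  d_{ij0})^2$ with every $e_i$ on the closed-gray surface, where $a_{ij}$
  marks lattice neighbours and $d_{ij0}$ the rigid spacing. The solver is
  damped block-coordinate descent: per contact, a pull-target average of
  the displacement anchor and neighbour-distance targets, followed by
  nearest-point reprojection; a step is accepted only if the energy does
  not increase, so the objective trace is non-increasing by construction.
  Defaults: `max_iter = 1000`, `tol_mm = 0.01` (maximum per-contact
  movement). Non-convergence within the budget is a *reported state*
  (`converged = FALSE` with the partial result), not an error, because on
  strongly shifted inputs the method legitimately fails to settle and the
  analysis must continue without it.

Sign ambiguity of eigenvectors and plane normals is resolved by casting
rays both ways and keeping the nearer surface hit; a double miss falls back
to the nearest surface point and flags the contact. CSF depth is modelled
by translating each projected centroid 0, 1 or 2 mm along the outward
normal of its nearest surface triangle. The *rigid* variant skips
projection entirely and instead removes tissue voxels above the grid
(best-fit plane of the rigid centroids, within the grid footprint), so the
contacts rest on, not inside, tissue; the voxel clip quantizes the cut, so
the pipeline rests the contacts and sheet exactly on the clipped tissue top.

## Synthetic data: what the phantoms emulate

The generators replace patient imaging while keeping every downstream
contract intact:

* **Head phantoms.** Nested closed surfaces (white ⊂ gray ⊂ closed-gray ⊂
  CSF) as subdivided icospheres, flat slabs, or a gyral slab whose top
  carries cosine-profiled sulcal grooves. The closing filter is honest:
  the phantom is rasterized at `voxel_pitch` (default 1 mm, a typical T1
  resolution), closed by FFT-based dilation-then-erosion with a ball, and
  re-surfaced from the voxel mask; CSF is an outward dilation. On the
  default gyral phantom (3 mm grooves, 3 mm radius) closing recovers about
  86% of the rasterized sulcal void — the shortfall is the expected
  circular-arc dimple over each groove mouth plus one-voxel discretisation.
* **Grids.** 8×8 contact grids at exact 10 mm pitch, 2.3 mm contacts. On
  spheres the lattice is a Chebyshev net (boundary rows marched along great
  circles, interior points by chord-circle intersection), which preserves
  *every* lattice edge at the exact 10 mm geodesic spacing — a physical
  grid is inextensible but shears freely.
* **Brain shift.** True centroids are retained; rigid centroids are the
  truth displaced inward (surface-normal or radial) by a uniform magnitude
  plus isotropic per-contact jitter. The default magnitude (4 mm) sits
  inside the range of reported median projection distances; the default
  jitter (0.3 mm) models sub-voxel CT centroid estimation noise, not
  localization-method error.
* **Artifacts.** Elongated Gaussian voxel clouds (default elongation 4,
  60 voxels, 0.6 mm transverse SD) recentred exactly on the rigid centroid,
  with per-contact axis wobble (default SD 5°) standing in for CT streak
  variability.
* **Recordings.** Biphasic rectangular pulses, first phase at the
  per-channel plateau and second negated, at 12,207 Hz with 1.2 ms phases
  (14 samples per phase), at least 50 ms of clean pre-stimulus window per
  pulse, plus white noise and linear drift. The desk default of 1000
  pulses scales down the clinical trains of 3,000–10,005 pulses while
  keeping averaged noise far below the smallest passive-contact plateaus.

What the phantoms deliberately do *not* emulate: real cortical geometry
(curvature spectra, sulcal branching), registration error between imaging
modalities, electrode-tissue interface impedance, heterogeneous or
anisotropic conductivity, spatially correlated brain shift, or
non-stationary recording artifacts. Passing tests therefore demonstrate
that the algorithms are implemented correctly and that the CSF/shift
effects behave as the physics dictates — not that a clinical model built
with this code is accurate for a given patient.

## Voltage extraction

Per channel: (1) each pulse is baseline-corrected to its mean pre-stimulus
signal 50 to 5 ms before onset; (2) all pulses are averaged time-locked to
onset; (3) the first difference of the average is z-scored against its own
window and contiguous runs with $|z| > 1.5$ mark the phase transitions
(onset = first sample after a run ends, offset = last sample before the
next begins; if noise produces extra runs, the three largest-|z| runs are
kept); (4) the first-phase plateau, shortened by three samples on each
side, is averaged. The extracted scalar keeps the first phase's sign.
Noiselessly synthesized trains round-trip exactly; under noise the error
obeys the $\sigma/\sqrt{n_{\text{pulses}} \cdot w}$ law for the trimmed
window length $w = 8$. Linear drift survives baseline correction only as a
bias equal to the drift rate times the window-to-plateau lag (~28.6 ms),
which lands in the regression intercept rather than the slope.

## Validation statistics

Simulated voltages at the passive (non-stimulating) contacts are compared
with the extracted recordings: element-wise absolute error summarised by
median and IQR; Brown–Forsythe (median-centred absolute deviations through
one-way ANOVA) for equality of variances; a Wilcoxon signed-rank test with
exact p by sign-assignment enumeration (a dynamic programme over doubled
mean ranks, so ties are handled exactly) for $n \le 20$ and a
tie-corrected normal approximation with continuity correction above, zeros
dropped; Holm–Bonferroni step-down control for families of comparisons;
and an ordinary least-squares regression of recorded on simulated voltage
(with intercept — the reported residual degrees of freedom $n - 2$ imply
one) reporting slope, slope SE, t, $R^2$, F with $(1, n-2)$ degrees of
freedom, and Pearson r. With simulated voltage as the predictor, a slope
above one means the model under-predicts. Pooling across stimulation
amplitudes divides voltages by $I_0$ ("1 mA normalization"), which leaves
slope and correlation invariant within a condition. All tests are
two-sided at $\alpha = 0.05$.

## The end-to-end experiment

`run_grid()` reproduces the comparison design on a slab phantom: the
"recorded" data are synthesized from the ground-truth model (true contact
positions, 0 mm CSF) plus drift and noise, then each projection method ×
CSF depth condition is meshed, solved, and regressed against those
recordings; the rigid model runs on the clipped geometry. Under the default
conditions the median absolute error and the regression slope both increase
strictly with modelled CSF depth, the 0 mm model's slope is closest to one,
and passive-contact voltage magnitudes shrink as CSF is added — the
shunting signature: the highly conductive film diverts current laterally
away from the tissue under the measuring contacts. A known regime limit:
if per-contact jitter grows toward ~1 mm, the stimulating pair's spacing
error (a few percent of dipole moment, i.e. a systematic scale error on
*all* passive voltages) can mask the 1 mm CSF shunting step, and the
error-versus-depth ordering is no longer guaranteed. That is a property of
the physics of the synthetic design, not a solver artifact, and is why
jitter defaults to centroid-noise scale.

## Numerical choices and degenerate inputs

* Rasterization classifies voxel/tet centres; volumes agree with analytic
  construction to well under the 3% meshing contract because grid planes
  snap to slab interfaces.
* Ray-parity containment tests use a fixed non-axis-aligned direction to
  dodge edge grazing on lattice-aligned meshes; nearest-point projection
  culls triangles by bounding-sphere distance.
* Discrete-ball morphology is only approximately monotone in the radius
  (digital balls at different radii are not exact scalings); the closing
  contract is therefore stated up to a one-voxel shell.
* Degenerate inputs fail loudly with the offending entity named: artifact
  clouds under 10 voxels, near-isotropic artifact axes, open surfaces fed
  to volumetric operators, missing conductivities, incompatible loads,
  phases too short to survive the 3-sample trim, flat channels.
* `solve_fem()` treats non-convergence of CG as an error (with the residual
  reported); `dykstra_project()` treats non-convergence as data.

## Reproducibility

Every stochastic stage takes an explicit integer seed and restores the
caller's RNG state; identical seeds give bit-identical phantoms, shifts,
artifacts, recordings and therefore reports. The `analysis/` scripts are
thin narrative drivers over the package functions and write their tables
under `results/`; `scripts/acceptance.R` re-derives the headline quantities
from scratch for a given `--seed`.
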