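---
title: "Multi-component finite-element modelling of breast biomechanics during running"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-component finite-element modelling of breast biomechanics during running}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mammotion` simulates the dynamic mechanical response of the female
breast during running with a multi-component nonlinear finite-element
model, and provides the surrounding analysis pipeline: a parametric
synthetic anatomy, hyperelastic material models, quasi-static gravity
loading, implicit transient dynamics driven by marker trajectories, a
gravity-free reference-configuration inverse algorithm, validation
metrics, and internal-stiffness sweep experiments.  This vignette is the
package's account of the underlying science: what is modelled, which
choices were open, and how they were resolved.

## The model

### Synthetic anatomy

Subject-specific surface-scan geometry is not distributed with the
package; `build_anatomy()` substitutes a parametric idealization whose
components and dimensions follow the anatomical literature:

* a curved chest-wall plate (the rigid torso surface) carrying a 25 mm
  subcutaneous soft-tissue layer;
* a pectoralis major slab directly behind the breast, about 12 mm thick
  at its centre and tapering below 5 mm at the edges;
* a breast modelled as a superellipsoid cap of adipose tissue (default
  base radius 60 mm, protrusion 50 mm -- roughly a C cup);
* 18 glandular lobes, drawn as stretched spheres with diameters sampled
  uniformly from 15--18 mm, arranged in two concentric circular arrays
  (6 inner, 12 outer) around the nipple axis, each connected by a
  tapering 2--4 mm duct to a circular body just beneath the nipple;
* a Cooper's-ligament network modelled as a closed three-dimensional
  structure: eight radial septa (L1--L8) plus an anterior sheet that
  follows the skin and a posterior sheet over the pectoralis, the
  latter restricted to the upper two-thirds of the breast where the
  breast attaches to the muscle;
* a 1.5 mm skin membrane over the entire outer surface.

Only the left half of the torso is generated; the sagittal plane
`x = 0` is a symmetry plane.  The lobe ring radii are derived from a
packing rule (adjacent lobe centres at least 1.1 lobe diameters apart),
and infeasible requests -- lobes that cannot be contained in the breast
-- raise an error rather than producing overlapping anatomy.

The mesh is a terrain-following structured grid: each plan-view column
carries a fixed stack of layers whose heights follow the chest-wall
curvature, the soft-layer/pectoralis interfaces and the breast cap, and
each hexahedral cell is subdivided into six path-tetrahedra
(Freudenthal subdivision), which is face-consistent across neighbouring
cells.  Every interface between components therefore shares nodes by
construction -- the glued, common-node contact the multi-component
model requires.  Component labels are assigned per element from
geometric predicates on element centroids; thin features (ligament
septa, ducts) widen their capture radius to the local element size so
they stay connected on coarse meshes.  The plan-view resolution is
4 mm in the central region containing the gland, ligament network,
pectoralis and neighbouring tissue and 8 mm elsewhere (the defaults),
matching the meshing rules of the source model; the analysis
configurations below run the same generator at reduced resolution.

What the generator does *not* emulate: real scanned torso shape and its
asymmetries, skin prestress, breast ptosis beyond the superellipsoid
family, inter-subject variation in gland/fat fraction, and the right
breast.  Tests that pass on this anatomy demonstrate the *pipeline's*
correctness and the qualitative mechanics, not subject-specific
magnitudes.

### Materials

All tissues are homogeneous, isotropic, nearly incompressible
hyperelastic solids with Poisson ratio 0.49.  Skin (500 kPa), the
soft-tissue layer (10 kPa), pectoralis major (10 kPa), Cooper's
ligaments (100 kPa) and glandular tissue (10 kPa) use the Neo-Hookean
energy

$$W = \tfrac{\mu}{2}(\bar I_1 - 3) + \tfrac{1}{d}(J-1)^2,
\qquad \mu = \frac{E}{2(1+\nu)}, \quad d = \frac{6(1-2\nu)}{E},$$

and adipose tissue uses the five-parameter (second-order) Mooney--Rivlin
polynomial with C10 = 0.31, C01 = 0.3, C11 = 2.25, C20 = 3.8,
C02 = 4.72 kPa.  Densities are 950 (adipose), 1040 (ligament), 1070
(gland) and 1050 kg/m^3 (pectoralis and soft layer).  Two points were
genuinely open:

* **Skin density** is not reported with this assignment; 1050 kg/m^3
  (muscle-like) is used and is configurable in `material_table()`.
* **Invariant convention for the Mooney--Rivlin term.**  The package
  uses the decoupled convention throughout: isochoric invariants
  $\bar I_1, \bar I_2$ of $\bar B = J^{-2/3} F F^\top$ plus the same
  volumetric penalty as the Neo-Hookean materials, with the adipose
  penalty coefficient derived from its small-strain effective modulus
  $E_\mathrm{eff} = 2\,(1+\nu)\,2(C_{10}+C_{01}) \approx 3.6$ kPa.
  No separate bulk datum exists for the adipose material, so deriving
  $d$ from $E_\mathrm{eff}$ keeps all six tissues on one convention.

The user-facing unit system is kPa / mm / kg/m^3; the solver converts
internally to the consistent mm--tonne--s system (MPa, tonne/mm^3)
with gravity 9800 mm/s^2.

### Finite-element formulation

The solver is total-Lagrangian with 4-node constant-strain tetrahedra.
At $\nu = 0.49$ plain linear tetrahedra lock volumetrically, and for
constant-strain elements an element-level mean-dilatation treatment is
an identity.  The package therefore evaluates the volumetric penalty on
the volume-averaged Jacobian of each *element patch* -- the six
tetrahedra subdividing one structured hexahedral cell:

$$W_\mathrm{vol} = \sum_e \frac{V_e}{d_e}\,(\bar J_{p(e)} - 1)^2,
\qquad \bar J_p = \frac{\sum_{e \in p} V_e J_e}{\sum_{e \in p} V_e}.$$

The isochoric part is evaluated per element (it is independent of $J$
in the decoupled convention).  The consistent tangent of the patch term
is exact and patch-local, so sparsity is preserved; with singleton
patches the scheme reduces to the standard displacement formulation.
A hanging-column refinement study drops from ~14% change under mesh
doubling (displacement formulation) to below 0.2% with the patch
treatment.  The isochoric material tangent is formed by central
differencing of the analytic first Piola--Kirchhoff stress at the
element level (step 1e-6), which reproduces finite differences of the
assembled residual to ~1e-9 relative -- comfortably within the 1e-4
consistency target enforced in the tests.

The skin is a membrane: incompressible plane-stress Neo-Hookean energy
times thickness and reference area, with the thickness stretch
eliminated analytically ($\lambda_3^2 = 1/\det C_{2\times 2}$) and no
bending stiffness.  This is a deliberate simplification: at 1.5 mm the
bending energy is negligible against the membrane term for the
deformations of interest.

Mass is lumped (row-sum), standard for soft-tissue implicit dynamics at
this scale.  Linear systems use a sparse Cholesky factorization of the
symmetrized tangent with an LU fallback; the assembly pattern is cached
across Newton iterations.

### Boundary conditions and loading

The rigid torso is realized as a *driven node set* (the chest-wall
surface): its X and Y displacements follow the prescribed trajectory
and Z is pinned, making contact resolution unnecessary -- the glued
interaction becomes shared degrees of freedom.  The sagittal plane
carries a symmetry condition (zero normal displacement) on all tissue
nodes; where a node is both driven and on the symmetry plane the torso
prescription wins, i.e. the torso slides along the symmetry plane when
mediolateral motion is prescribed.  This mirrors the standard
half-model-plus-lateral-drive compromise.  Gravity defaults to acting
on *all* deformable components (the alternative -- restricting it to
the breast interior -- is a per-component switch in
`boundary_conditions()`), since omitting the self-weight of the soft
layer and pectoralis would leave them unphysically undeformed.

Quasi-static gravity loading uses incremental load stepping with full
Newton--Raphson iterations, converged when the free-DOF residual drops
below 1e-6 of the external force norm; non-converged increments are
bisected (up to four times).  Transient dynamics uses Newmark average
acceleration ($\gamma = 0.5$, $\beta = 0.25$; the numerical dissipation
of the commercial solver the model descends from is undocumented, so
the non-dissipative scheme is chosen and stated), full Newton per step,
a 0.005 s step, and the gravity equilibrium as initial condition.  The
prescribed motion is interpolated with cubic splines, because the
implicit integrator differentiates the prescribed history twice and
slope kinks of linear interpolation ring in the driven accelerations.
Damping is off by default and in every validation run; a
mass-proportional Rayleigh flag exists for numerical robustness only.

### The synthetic running drive

`build_synthetic_gait()` emulates the vertical and mediolateral motion
of a clavicle marker at 120 Hz with a 0.38 s half gait cycle.  The
vertical waveform has one crest (`t2`) and one trough (`t4`) per
half-cycle; the mid-phase instants define the `t1`/`t3` analogues (on a
clavicle trace alone, foot-off and foot-strike cannot be detected, so
these are waveform-phase definitions, not gait detections).  Its
defaults encode the clavicle kinematics of treadmill running at
moderate speed:

* vertical peak-to-peak 70 mm: with the 0.38 s half-cycle this puts
  the crest near free fall ($\omega^2 A/2 \approx g$), the physical
  signature of the flight phase -- at `t2` the breast springs upward by
  its released gravity sag;
* a mild second-harmonic asymmetry (0.1), deepening the trough
  consistent with the modest crest/trough displacement asymmetry of a
  running clavicle;
* a foot-strike braking pulse: a 5 mm Gaussian dip (SD 0.03 s) centred
  on each trough.  The ground-reaction braking of running concentrates
  a large upward acceleration at `t4` without unloading the crest; a
  smooth low-harmonic wave cannot carry this feature, and without it
  the peak-stress timing of the ligament network smears across the
  late half-cycle;
* mediolateral sway of 15 mm peak-to-peak at the full-cycle frequency
  -- minor relative to the vertical drive, as the near-vertical peak
  acceleration of a running clavicle implies;
* additive Gaussian marker noise (SD 0.5 mm), removed in the pipeline
  by the zero-lag Butterworth filter exactly as for real marker data.

Because the model is undamped, an impulsive start would ring
indefinitely in the energy-conserving integrator.  The pipeline
therefore tapers the drive on with a C2 quintic smoothstep over the
first half-cycle and analyses gait events in the *second* half-cycle.

### Gravity-free reference configuration

A scanned standing posture is already deformed by gravity.
`estimate_unloaded()` recovers the stress-free reference by fixed-point
iteration: initialize by applying reversed (upward) gravity to the
loaded geometry, then repeatedly deform the current reference estimate
under downward gravity, compare with the target surface, and move the
reference nodes by the relaxed mismatch.  The literature source of the
method states no tolerance, step factor or iteration cap; the package
exposes all three (`tol = 0.1` mm maximum breast-surface mismatch,
`relaxation = 1`, `max_iter = 30`).  The upward-gravity solve is
treated as the initializer only, not as part of every iteration --
with it inside the loop the scheme would no longer be a fixed-point
iteration on the reference geometry.  The mismatch metric is the
maximum nodal distance over the *breast surface* node set, since only
the scanned surface is observable in practice.  Divergence (three
consecutive residual increases) raises an error carrying the history;
element inversion during an update halves the relaxation automatically.

### Validation metrics

* **Zero-lag Butterworth filter**: a 2nd-order low-pass applied forward
  and backward (effective 4th order, zero phase), cutoff 6 Hz applied
  directly -- the common biomechanics convention; a cutoff-correction
  flag implements the $(2^{1/2}-1)^{-1/4}$ pre-warp for users who want
  the cascaded -3 dB point at exactly 6 Hz.  Reflective edge padding
  keeps the filter transient off the data.
* **RMAE**: mean of $|D_{EXP} - D_{FEM}| / |D_{EXP}|$ over retained
  frames of one axis.  Frames with $|D_{EXP}|$ below 0.5 mm are
  excluded and counted -- the ratio is unstable near zero, a case the
  defining formula does not address.  The normalization is the mean
  over retained samples.  Displacements are taken relative to the
  first (standing) frame before comparison.
* **Surface-to-surface distance**: for every simulated node and frame,
  the nearest point on the reference frame's triangulated surface
  (exact point-to-triangle projection), averaged over nodes and frames.
  The defining sum is sometimes written with squared norms yet named an
  average Euclidean distance; the default here is the mean *unsquared*
  Euclidean distance, with `mode = "squared"` available.  The C++
  implementation prunes triangles by bounding-sphere distance and is
  tested to 1e-9 against an exhaustive all-triangle scan in R.  The
  averaged node set defaults to the breast surface.

### Regional analyses and stiffness sweeps

Regions of interest are defined geometrically on the synthetic anatomy
(they are only marked on figures in the source setting): the ligament
contact areas (posterior sheet centre attached to the pectoralis,
posterior sheet rim backed by adipose, and ligament in contact with the
gland), pectoralis patches (anterior centre + eight sectors; posterior
centre + rim), gland rear/bottom/top/front, and the adipose shell
adjacent to the gland.  Regional summaries are volume-weighted mean von
Mises histories with peak values, times and locations.  The
per-direction ligament maxima (`ligament_direction_maxima()`) follow
the source analysis: the maximum-stress element of each septum's
*anterior* half at the `t4` frame, whose history is then checked for
its peak time.

`stiffness_sweep()` re-runs the transient simulation over Young's
modulus grids of five levels -- 5--15 kPa in 2.5 kPa steps for the
gland, 80--160 kPa in 20 kPa steps for the ligaments -- holding all
other materials fixed, extracts the nipple total displacement at the
four gait events, and fits displacement against stiffness by ordinary
least squares with Pearson correlations.  Representative material
points for the per-component kinematics are: the nipple surface node;
the most anterior ligament element near the nipple axis (the anterior
sheet under the skin); the element nearest the gland's volume centroid
(the lobe ring); the most anterior pectoralis element; and the driven
clavicle node.  The element-based points average their four nodes, so
they are true material points of the component rather than interface
nodes shared with a neighbour.

## Numerical choices and problem sizes

* Newton tolerance 1e-6 (relative to the external force norm), at most
  25 iterations per increment/step, 4 automatic bisections.
* Mean-dilatation patches = the 6-tet hexahedral subdivision groups.
* Tangent: analytic stress, central-difference material tangent
  (1e-6 step); patch volumetric tangent exact.
* Time step 0.005 s (the reference protocol); full runs are 600 steps
  (3 s), the packaged analysis configurations cover ramp plus one
  analysed half-cycle (146 steps).
* The default anatomy meshes at 4/8 mm (about 33k tetrahedra).  The
  packaged analysis configuration runs the same generator at 10/16 mm
  (about 6k tetrahedra, `default_config()`); the test-suite stiffness
  sweeps use 16/26 mm (about 2.5k tetrahedra) -- sizes chosen so the
  full validation suite runs interactively on one CPU.  Element counts
  are configuration, not science.
* Determinism: anatomy and gait are seeded; given a configuration and
  seed, sweep tables are bitwise reproducible.

## Known limitations

* Constant-strain tetrahedra with patch mean dilatation still stiffen
  bending-dominated responses on coarse meshes; absolute displacement
  and stress magnitudes on the synthetic anatomy are not calibrated to
  any subject.
* The membrane skin carries no bending stiffness and no prestress.
* The ligament septa are voxel-captured at the local element size, so
  their effective thickness on coarse meshes exceeds the nominal 3 mm.
* The undamped model never forgets residual transients entirely; the
  smooth-start ramp reduces them below the analysis signals but does
  not eliminate them.
* The voxel-captured ligament network occupies a larger volume
  fraction than real breast anatomy, so the relative influence of
  ligament stiffness on surface motion is somewhat over-represented:
  per grid step, the ligament sweep moves the nipple about as much as
  the gland sweep, whereas anatomically the (larger) gland would be
  expected to dominate slightly.
* Self-contact, bra--skin contact, viscoelasticity, anisotropy and
  active muscle are out of scope.
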