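---
title: "Methods: prestressed modal analysis of the cartilaginous nasal septum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prestressed modal analysis of the cartilaginous nasal septum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septamodal)
```

## The model

`septamodal` treats the quadrangular (cartilaginous) nasal septum as a thin,
flat, linearly elastic plate lying in the sagittal midplane. The plate's
anatomical frame is x = posterior→anterior, y = inferior→superior, and the
out-of-plane axis z is lateral — the direction in which a septum deviates.
The bony margins (perpendicular plate of the ethmoid posteriorly, vomerine
groove and maxillary crest inferiorly, and the nasal bones over the posterior
part of the dorsum) are far stiffer than cartilage and are modelled as
rigidly fixed; the dorsal and caudal margins are free. The anterior septal
angle (ASA) is taken as the nasal tip and can optionally be supported by a
grounded spring of 20 kN/m per axis, representing the elastic recoil of the
lower lateral cartilages; the spring constant follows the end-loaded
cantilever formula k = 3EI/L³ = E·w·h³/(4L³).

Cartilage is modelled as homogeneous, isotropic and linearly elastic
(E = 5 MPa, ν = 0.32, ρ = 2000 kg/m³), a standard simplification valid for
moderate strains; the plate thickness defaults to a uniform 2 mm. Because
only *relative* displacements within a mode shape matter for classifying
deviation patterns, the absolute material scale does not affect the
taxonomy — it only scales frequencies (as √E and 1/√ρ, a property the test
suite checks end-to-end).

For a flat midplane the in-plane (membrane) and out-of-plane (bending)
responses decouple exactly. The package therefore assembles two families of
operators over the same triangulation:

* **Membrane**: constant-strain triangles (CST), 2 DOF/node (u, v), with a
  plane-stress constitutive law and consistent mass.
* **Bending**: discrete Kirchhoff triangles (DKT), 3 DOF/node
  (w, θx = ∂w/∂y, θy = −∂w/∂x), with flexural rigidity
  D = Et³/(12(1−ν²)), consistent translational mass from the linear
  interpolant of w and rotary inertia ρt³/12 on the rotations. The rotary
  terms are physically negligible for a thin plate but keep the mass
  operator positive definite, which the solver relies on.

The DKT element is validated in the tests by its exact rigid-body null
space and by exact energy reproduction of constant-curvature and
constant-twist patch fields; the assembled solver is validated against the
closed-form Kirchhoff frequencies of a simply supported rectangular plate,
f_mn = (π/2)(m²/a² + n²/b²)√(D/ρt).

## Preload and geometric stiffness

Mimicking the two-step solution procedure of commercial codes (a general
static step followed by a linear-perturbation frequency step), the package
first solves the static membrane problem K_m u = f for one of two frontal
loadings, recovers per-element stresses, and assembles the geometric
(initial-stress) stiffness K_g = Σ_e t_e ∫ (∇w)ᵀ σ_e (∇w) dA on the
transverse DOFs. The prestressed eigenproblem is then
(K_b + K_g)φ = ω²M_b φ. The prestress is linearized — there is no geometric
nonlinearity in the static solve — and K_g is exactly linear in the stress
state (zero stress gives K_g = 0).

The two load cases are strictly in-plane, since only in-plane preload can
influence the bending modes of a flat plate:

* **Tip couple** ("anteroposterior loading"): equal and opposite forces
  with components of 1 N in each axis, applied at the two boundary nodes
  flanking the tip, i.e. a pure force couple (zero net force, non-zero
  moment). The literature description of this load is ambiguous; the
  package's default is the literal mechanics reading of "a couple of
  forces of 1 N each in both the vertical and horizontal axes". A variant
  carrying a *net* posterior push was considered and rejected as the
  default: a net in-plane force of order 1 N concentrated at the free thin
  plate corner exceeds the corner's local buckling load (of order
  π²D ≈ 0.04 N), so the linearized prestressed operator loses positive
  definiteness for the free-tip model and possesses no vibration modes at
  all. The solver reports this situation as an explicit "buckled under
  preload" error, and `build_load_vector()` still lets the user apply any
  force pair to explore it.
* **Dorsal/caudal edge pressure**: a uniform 2000 Pa acting *in-plane* and
  inward on the free dorsal and caudal edges, integrated consistently as
  p·t per unit edge length. A lateral (out-of-plane) interpretation of
  this pressure would not influence the eigenmodes at linear order and is
  deliberately not offered.

At these magnitudes the preload is a small perturbation: the test suite
checks that removing K_g entirely does not change the classification
sequence of the default model, which is also why the two load cases yield
mode-for-mode identical classifications.

## Geometry, meshing, and landmarks

Only the nasal-bone overlap length of the midplane outline is anchored to a
measured value (14 mm, inside the normal 3–15 mm range, enforced as a hard
bound). The remaining dimensions of the idealized outline are documented
surrogate defaults chosen as representative adult values — inferior edge
32 mm, posterior height 22 mm, caudal edge 20 mm with a 10° posterior tilt
— and are fully configurable. The default set was frozen after verifying
that the classification sequence it produces is stable across the
neighbouring dimension range; the package's regression test pins the
resulting sequence, and any geometry change is expected to re-run it.

Because no constrained-triangulation library is available in the target R
stack, meshing uses a transfinite (Coons-patch) map over the outline's four
macro-sides (inferior, caudal, dorsal, posterior), subdividing each
quadrilateral cell along its shorter diagonal. Boundary sample points
always include the outline's own vertices, so the mesh boundary is a
refinement of the outline polygon and the meshed area equals the polygon
area to round-off (asserted at 10⁻⁹ relative). Inverted cells — possible
only for extreme outline distortions — abort meshing with the offending
location named. Boundary node sets are carried per anatomical label, and
landmark regions (ANS, bony–cartilaginous junction, vomer–ethmoidal
junction, vomerine groove) collect elements whose centroid lies within a
configurable 3 mm radius of the landmark (for the groove: of the vomer
segment).

## Eigen extraction

Both generalized symmetric eigenproblems are reduced by a Cholesky
congruence of the mass matrix and solved densely with LAPACK, which is
deterministic (bit-reproducible across runs, no iterative randomization)
and fast at the problem sizes the package targets (the default 1.5 mm mesh
gives ≈ 370 nodes ≈ 10³ DOF per family; a full pipeline run takes a few
seconds on one core). Mode shapes are returned mass-normalized
(φᵀMφ = 1). The lowest 10 modes of the merged bending + membrane spectrum
are analyzed by default — lower modes need less energy and so dominate
observed deformation — with exact frequency ties broken bending-first. A
negative prestressed eigenvalue raises the "buckled under preload" error
rather than returning a complex frequency.

## Classification

Membrane modes carry no transverse displacement: a mode whose
transverse-to-total modal-mass ratio falls below τ = 0.1 is reported as an
in-plane "dash" mode with no deformation shape. For the flat decoupled
plate this test is binary (the ratio is ≈ 1 for bending modes and exactly 0
for membrane modes); the threshold only becomes meaningful for synthetic
mixed vectors, which is why its exact value is uncritical and configurable.

Out-of-plane modes are classified by the sign structure of w: nodes with
|w| < ε·max|w| (ε = 0.02) form the nodal band, and the remaining nodes are
partitioned into connected components of the mesh adjacency graph
restricted to same-sign edges. One lobe is a septal tilt (type I), two
lobes a C-shape (type II), three an S-shape (type III); higher counts are
reported as type III with a warning, since the clinical taxonomy stops at
the S-shape. Nodal lines are traced through the sign-crossing points
interpolated on mesh edges (robust on coarse meshes, where few nodes fall
inside a narrow band) and chained triangle-wise; the principal axis of each
line distinguishes anteroposterior from cephalocaudal C-shapes. The whole
classification is invariant under mode sign flips and amplitude rescaling,
which the tests assert, since eigenvector sign and scale are arbitrary.

Modal von Mises stress is evaluated per element — surface bending stress
6m/t² at z = t/2 for bending modes, membrane stress for in-plane modes —
and summarized per landmark region, ranked by peak value with the region
containing the global maximum first. Because mode shapes have arbitrary
amplitude, **only hotspot locations and rankings are meaningful, never
absolute stress values**; all outputs carry this caveat implicitly by
reporting modal stress in arbitrary units.

One further caveat is propagated to users of the comparison report: for
the third mode the source literature's running text and its printed table
disagree about which tip condition shows a tilt versus a C-shape. The
package reports both models' computed labels side by side
(`compare_models()`) and does not attempt to resolve that discrepancy.

## Synthetic patient-like models

The generator stands in for a CT-derived patient-specific model, which
cannot be redistributed. It perturbs the outline by a seeded, low-order
harmonic radial field (amplitude 0.05 of the mean outline radius by
default) and replaces the uniform thickness by a seeded harmonic field with
mean exactly 2 mm and ±25 % amplitude — the default amplitudes are chosen
as realistic anatomical variation while keeping the polygon simple and the
transfinite mesh well conditioned. Harmonics, rather than arbitrary noise,
keep outlines smooth; a perturbation that self-intersects is retried with
halved amplitude before failing. Fixed seeds give bit-reproducible models.

What passing tests on these synthetic models *does* show: the pipeline is
robust to smooth geometry/thickness variation of realistic magnitude and
keeps producing only the dash/I/II/III taxonomy. What it does *not* show:
agreement with any real patient's septum — the generator is a surrogate,
not a morphometric model, and carries no population statistics, no
anisotropy, and no true parasagittal curvature.

## Numerical choices and limitations

* Tolerances: static solves are accepted at relative residual < 10⁻¹⁰;
  eigenpairs at dimensionless residual < 10⁻⁸; mass-orthonormality at
  10⁻⁸. All are met with large margin by the direct solvers.
* Degenerate inputs: zero-area triangles, non-simple polygons, empty
  landmark regions, out-of-range overlap lengths, and all-zero transverse
  fields are rejected with descriptive errors rather than propagated.
* Problem sizes: the shipped tests use 2–4 mm meshes for unit checks, the
  1.5 mm default mesh for study-level checks, and plate fixtures up to 28
  divisions per side; these sizes put every frequency of interest within a
  few percent of its refinement limit while keeping a full test run under
  a minute. The septum spectrum's maximum change between successive mesh
  halvings decreases monotonically (it is ≈ 2.6 % between 1.6 mm and
  0.8 mm, dominated by one membrane mode); the plate fixture reaches the
  < 2 % per-refinement regime within the sizes tested.
* Kirchhoff (thin-plate) kinematics: no transverse shear (Mindlin)
  deformation, no curved-shell coupling, no anisotropic or viscoelastic
  cartilage, no bony-vault compliance. These match the scope of the
  modelled study; they matter most for thick or strongly curved septa.
* The linearized prestress cannot follow post-buckling paths: fracture and
  overlap ("septal concertina") geometry are interpreted from stress-line
  patterns, not simulated.
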