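---
title: "Meniscal tear mechanics: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meniscal tear mechanics: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Menisci transmit roughly half of the compressive load across the
tibiofemoral joint. Because their collagen fibers run circumferentially,
axial compression that squeezes the wedge-shaped cross-section between the
femoral condyle and the tibial plateau is converted into circumferential
("hoop") tension. A *longitudinal* tear runs parallel to the fibers and
barely interrupts this load path; whether it heals is thought to depend on
whether the stress state presses its two faces together. A *radial* tear
cuts the fibers and concentrates stress at its inner apex. `kneefem`
implements a complete, self-contained finite-element pipeline for studying
these mechanisms across the screw-home phase of knee flexion (0-30
degrees): synthetic parametric geometry, structured tetrahedral meshing,
a transversely isotropic meniscal material, frictional contact against a
rigid femur and tibia, tear insertion by node splitting, and the
stress-based tear metrics.

# The synthetic knee

No subject-specific segmented geometry ships with the package; the
generator (`knee_params()`, `knee_geometry()`) produces an anatomically
plausible stand-in:

* **Coordinates.** Origin at the tibial plateau centre, +x lateral,
  +y anterior, +z proximal, lengths in mm (right knee by default; a
  `handedness` switch produces the exact sagittal mirror image).
* **Bones are rigid.** The tibial plateau is the plane z = 0; each femoral
  condyle is a sphere (default radii 37 mm medial, 35 mm lateral - the
  scale of the distal femoral extension facet). Rigid bones never appear as
  meshes: they act through bonded boundary conditions and the rigid-femur
  degrees of freedom.
* **Cartilage.** An isotropic elastic layer (E = 13 MPa, nu = 0.42),
  2.5 mm thick, on both sides: rectangular blocks on the plateau, spherical
  shell caps on the condyles. "No tangential motion at the cartilage-bone
  interface" is realised by fixing the tibial-side bone face and slaving
  the femoral-side bone face rigidly to the femur.
* **Menisci.** C-shaped solids swept from a right-triangle wedge
  cross-section: flat inferior face congruent with the tibial cartilage
  surface, sloped superior face, vertical peripheral wall. The wedge tapers
  towards the inner rim; a small inner-rim height (0.5 mm default) keeps
  the swept tetrahedra non-degenerate. Default annuli: medial 9-22 mm over
  a 300 degree arc, lateral 7-18 mm over 270 degrees, peripheral heights
  6 / 5.5 mm. Each arc is parameterised in a compartment frame whose first
  axis points to the knee midline, so the C-opening faces the
  intercondylar area and the medial/lateral constructions are mirror
  images. The anterior and posterior ends are flat terminal faces that
  carry the insertional-ligament attachments.
* **Vertical registration.** The femur is lowered until its cartilage just
  touches its support envelope (tibial cartilage or meniscus) - zero gap,
  zero interpenetration at the reference pose. With the default shapes the
  first contact is on the meniscal wedge at mid-annulus, with ~0.1-1 mm of
  clearance at the cartilage-cartilage centre; the free varus-valgus and
  mediolateral femur DOFs then balance the two compartments under load.
* **Landmarks.** Medial/lateral epicondyles and the adductor tubercle are
  carried on the femur for landmark-based registration
  (`landmark_transform()`, a Kabsch SVD fit).

The generator's `random_seed` only drives an optional low-order Fourier
roughness of the meniscal outer wall and defaults to zero amplitude:
the default geometry is fully deterministic.

## Flexion kinematics

The femur pose (`pose_femur()`) is a rotation about the fixed axis through
the two condylar sphere centres, composed with a screw-home internal
rotation of 5 degrees accrued linearly from 0 to 20 degrees of flexion
(constant thereafter) about the vertical axis through the *medial*
compartment centre - a medial-pivot model, which makes the lateral
compartment the more mobile one, as expected for the screw-home mechanism.
Because the condyles are spheres and the flexion axis passes through their
centres, the articular surface is invariant under flexion; flexion
influences the solution through the screw-home component and the femoral
cartilage cap (which is generated about the posed downward axis - exact
for spherical condyles). A known limitation follows: the posterior
migration of the contact point with flexion that subject-specific condyles
produce is not represented; flexion-angle effects in this synthetic knee
are carried by the screw-home rotation alone.

# Materials

Both tissues are linearly elastic. Cartilage is isotropic
(E = 13 MPa, nu = 0.42). The meniscus is transversely isotropic with the
fiber (circumferential) direction as the symmetry axis: in-plane
E = 20 MPa, nu = 0.2, G = 8.3 MPa; along the fiber E = 150 MPa, nu = 0.3,
G = 57.7 MPa. The compliance is assembled in the local frame (axis 1 =
fiber) and rotated to the global frame by the fourth-order (Bond)
transformation; Voigt ordering is (11, 22, 33, 23, 13, 12) with
engineering shear strains throughout.

Two conventions in these constants deserve note. First, the printed
in-plane shear modulus (8.3 MPa) differs by 0.4% from the exact
transverse-isotropy value E/(2(1+nu)) = 8.33 MPa; the package uses the
printed value, so the material is very mildly tetragonal and the local
in-plane axes are fixed deterministically (axis 3 = global z projected off
the fiber). Second, the fiber-plane Poisson ratio is interpreted as the
major ratio nu_12 = 0.3 (fiber stretch contracting the plane), which is
thermodynamically admissible with the printed moduli; the minor-ratio
reading cannot be recovered from the printed constants and is not used.
Both choices are configurable.

# The finite-element model

* **Elements.** Linear (constant-strain) tetrahedra from a structured
  Freudenthal (6-tet) split of swept hexahedral grids - face-consistent,
  hence bit-for-bit reproducible meshes. Default resolution: 60
  circumferential x 12 radial x 2 vertical divisions per meniscus and
  10 x 10 x 2 cartilage grids.
* **Springs.** Each meniscal horn face is tied to its tibial insertion
  point by a tension-only linear spring (lateral anterior 216, lateral
  posterior 130, medial anterior 169, medial posterior 207 N/mm); slack
  length equals the reference distance, so the springs are force-free in
  the unloaded state (no pretension is modelled).
* **Contact.** Node-to-surface penalty contact with regularised Coulomb
  friction (mu = 0.02) between every articulating pair (meniscus-femoral
  cartilage, meniscus-tibial cartilage, cartilage-cartilage, and the two
  faces of a tear). Forces are distributed to the target facet nodes with
  barycentric weights, so contact transmits equal and opposite forces and
  global equilibrium holds to the solver tolerance. Contact normals are
  barycentric interpolations of area-weighted vertex normals: on a faceted
  curved surface, per-face normals leave gradient kinks that stall Newton
  iterations, while the smoothed field restores a continuous gap function.
* **Friction law.** |f_t| = mu f_n tanh(k_t |slip| / (mu f_n)) from an
  elastic anchor - a smooth regularisation of the Coulomb cone with a
  consistent pseudo-potential. Anchor states are history variables,
  committed between (sub-)steps, never inside a Newton iteration. The
  regularisation scale (`penalty_tangent`, default one tenth of the normal
  penalty; the bundled studies use 2 N/mm^3, giving a yield stretch of a
  few hundredths of a millimetre at physiological pressures) trades
  sharpness of the stick-slip transition against conditioning.
* **Load case.** The tibia is fully fixed. The femur is rigid with three
  free DOFs - mediolateral translation, varus-valgus rotation, and the
  load-driven axial translation - and the compressive load (750 N = one
  body weight for the 75 kg reference subject; 375 N = half) is applied at
  its reference node along the tibial long axis. Flexion-extension,
  internal-external rotation and anteroposterior translation are imposed
  by the pose.

## Solver

The problem is geometrically linear with three nonlinearities: contact
activation, friction, and the tension-only springs. With frozen friction
anchors the system is the stationarity condition of a convex energy
(elastic strain energy + load potential + contact penalty + the Huber-like
friction pseudo-potential), which the solver exploits: Newton iterations
with an Armijo line search on the total potential energy, switching to
residual-norm descent near equilibrium where energy differences fall below
round-off. Robustness devices, none of which affect the converged
solution: a wide contact-activation band in the first iterations (stiffness
without force, so the initially floating femur is well-posed), tangent-only
Levenberg damping, step limiting, and friction-anchor re-commits when an
iteration stagnates against stale anchors. Convergence is declared at a
force residual below `rtol` times the applied load; the default
rtol = 2e-3 (1.5 N at body weight) sits above the residual floor of the
faceted-penalty formulation (about 0.6-1.2 N at the study resolutions,
scaling with the contact penalty) while meeting every physical acceptance
tolerance in the package (e.g. 0.5% on global equilibrium at full
extension). Tighter tolerances are accepted but cost disproportionate
iterations against that floor. Penetration is monitored against 1% of the cartilage thickness
(0.025 mm).

Default penalties: normal 100x the softest participating modulus per
cartilage thickness (520 N/mm^3), which keeps the residual penetration
below 1% of the layer thickness at the bundled resolutions; halving or
doubling it changes the solution by much less than the
mesh-discretisation error.

# Tears

Tears are inserted on existing element faces (snap-to-mesh) by node
duplication (`insert_tear()`): the interior tear-surface nodes are
duplicated, elements on the positive side reconnect to the copies, the
tear front (tip/apex) nodes remain shared, and the two faces are enrolled
as a frictional self-contact pair. Element count and total volume are
exactly conserved; re-merging the node pairs reproduces the intact mesh
bit-for-bit. Longitudinal tears lie on the cylinder s = 5/6 (the centre of
the outer/red third, with equal-tercile zones); stable/unstable lengths
are 7/14 mm, snapped to the nearest whole number of element edges (the
achieved length is always reported). Radial tears lie on the radial plane
through the circumferential centre of their region, start at the inner rim
and extend 1/6 (stable) or 1/2 (unstable) of the local rim width. Both are
full thickness. The default radial division (12) places both the s = 5/6
line and the 1/6 rim-width extent on element boundaries.

# Outcome measures

* `sample_transect()`: maximum principal stress (the hoop-stress
  indicator) sampled from the inner rim (normalised length 0) to the outer
  rim (1) along the mid-arc, mid-height line of a region. Sampling height
  and line are configurable; values are element-wise constant for linear
  tetrahedra.
* `tear_surface_difference()`: mean fiber-direction normal stress over the
  elements adjacent to each face of a longitudinal tear; the difference
  (outer - inner) is classified *favourable* when strictly positive (the
  faces are pressed together); a tie is unfavourable. The max-PCS means
  are reported alongside as a cross-check.
* `apex_stress_delta()`: mean max-PCS over the elements adjacent to the
  tear front, minus the same elements in the intact run (element identity
  is preserved by tear insertion). Positive = added tension.
* `compartment_contact_metrics()`: peak compressive minimum principal
  stress per tibial compartment and the active contact area (sum of facet
  areas carrying contact force).
* `segment_displacements()`: anteroposterior displacement of the
  anterior/posterior segment centroids and mediolateral displacement of
  the most external midsection point between two flexion poses; positive
  values are anterior and medial.

# Verification and study sizes

The package verifies itself with numerical experiments
(`material_test_uniaxial()`, `material_test_shear()`,
`block_friction_test()`, `hertz_contact_test()`) and the test suite:
single-sample tests recover all six meniscal and both cartilage constants
to better than 0.5%; the patch test is exact to machine precision; a
sliding block recovers mu to 5%; a mirrored knee yields the mirrored
solution; and the femoral settlement changes by less than 2% between
successive mesh refinements.

Two related verification targets are not met at desk scale and are
reported as known failures. First, the force-approach curve of a rigid
sphere pressed into an elastic block overestimates the Hertz half-space
closed form by 13-24% in every configuration that fits the test budget. The bias decomposes into
the finite bonded-base domain (decaying roughly with one over the domain
depth; extrapolating two domains towards the half space leaves about
+12%) and the well-known over-stiffness of constant-strain tetrahedra
under indentation (shrinking roughly linearly with element size: +37% at
3.1 mm elements, +12.8% at 2.0 mm). Closing the remaining gap requires
domains beyond 100 mm together with sub-millimetre elements - far beyond
a test-suite-sized problem. Second, and for the same root cause, the femoral
vertical settlement of the knee model changes by more than 2% between the
suite's successive mesh refinements: the settlement is dominated by the
contact-layer compliance, whose discretisation error shrinks only
linearly with element size. Both tests are kept at their stated
assertions (10% and 2%) and fail; the penalty law itself, friction
recovery, global equilibrium and frame indifference are all verified
independently, and stress-based outcome measures (which average over
elements away from the contact integration points) are far less
sensitive, as the stable transect fields across refinements show.

One qualitative reproduction is also reported as a known failure: in this
synthetic knee, *longer* longitudinal tears show the *larger*
outer-minus-inner hoop-stress differences (both lengths remain favourable
at almost every site), whereas the subject-specific study this package
follows found shorter tears more favourable. In the spherical-condyle
geometry the hoop field around the tear is smooth, so cutting more fibers
diverts more tension to the outer rim; reproducing the reported ordering
evidently requires the irregular condylar and meniscal surfaces of real
knees, which load the inner flap of long tears. The lateral-over-medial
favourability ordering, the apex stress concentrations growing with
radial tear length, and the apex elevation over the intact state are all
reproduced.

The qualitative tear study (both menisci x three regions x both tear types
x both stabilities at 0/20/30 degrees under one body weight,
`tear_matrix_study()`) runs at a coarse study resolution - 30 x 12 x 2
meniscal and 6 x 6 x 2 cartilage grids, one intact solve per angle and
every torn cell warm-started from it - chosen from a convergence study as
the coarsest mesh whose refinement changes the femoral settlement by less
than 2% while resolving every tear with at least two element edges. Its
outputs are ordering statements (which configuration is more favourable),
not magnitudes.

# What the synthetic knee does and does not show

Passing the qualitative suite shows that the *mechanisms* - hoop-stress
redirection around longitudinal tears, favourable compression of short
tears, apex concentration at radial tears growing with tear length - are
reproduced by the model's physics on an idealised geometry. It does not
validate subject-specific magnitudes: the published per-subject numbers
(compartment peak pressures, segment displacement tables) depend on one
individual's segmented surfaces and imaged kinematics, which this package
deliberately replaces with an analytic stand-in. Spherical condyles, a
flat plateau, linear elasticity, the absence of the major knee ligaments
and of poroelastic time dependence are all simplifications carried over
from, or added to, the modelling tradition this package follows.

# Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| rtol (force residual / load) | 2e-3 | above the formulation floor; see Solver |
| penetration tolerance | 0.025 mm | 1% cartilage thickness |
| normal penalty | 520 N/mm^3 | 100x softest modulus / thickness |
| tangential penalty | normal/10 (studies: 2) | yield stretch ~0.01-0.05 mm |
| friction mu | 0.02 | articular cartilage lubrication |
| contact activation band | 0.5 mm, first 3 iterations | femur well-posedness |
| mesh (default) | 60x12x2 menisci, 10x10x2 cartilage | tear snapping <= one edge |
| mesh (study) | 30x12x2 menisci, 6x6x2 cartilage | <2% refinement change |
| screw-home coupling | 5 degrees over 0-20 | medial-pivot literature range |
| body weight | 750 N | 75 kg reference subject |
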