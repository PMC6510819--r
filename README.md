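# kneefem

Finite-element analysis of intact and torn menisci under weight bearing,
across the screw-home phase of knee flexion (0-30 degrees).

## The problem

The menisci convert tibiofemoral compression into circumferential (hoop)
tension carried by their collagen fibers. Whether a meniscal tear is a
candidate for non-operative treatment is thought to depend on the local
mechanics: a *longitudinal* tear (parallel to the fibers) heals more
readily when the stress field presses its two faces together, while a
*radial* tear (cutting the fibers) concentrates tension at its inner apex
and tends to propagate. `kneefem` is a self-contained R implementation of
this analysis for biomechanics researchers: it generates a parametric
synthetic knee (rigid bones, isotropic cartilage layers, transversely
isotropic C-shaped menisci anchored by tension-only insertional-ligament
springs), meshes it with linear tetrahedra, solves the static frictional
contact problem under axial load, inserts full-thickness tears by node
duplication, and computes the stress-based tear-stability metrics.

## The model in brief

* Linear elasticity; cartilage isotropic (E = 13 MPa, nu = 0.42), meniscus
  transversely isotropic about the circumferential fiber direction
  (in-plane E, nu, G = 20 MPa, 0.2, 8.3 MPa; fiber direction 150 MPa, 0.3,
  57.7 MPa).
* Rigid bones: the tibia fully fixed, the femur free in mediolateral
  translation, varus-valgus rotation and axial (load-driven) translation;
  compressive load along the tibial long axis (750 N = one body weight,
  375 N = half).
* Insertional ligaments as tension-only linear springs (lateral anterior /
  lateral posterior / medial anterior / medial posterior = 216 / 130 /
  169 / 207 N/mm).
* Node-to-surface penalty contact with regularised Coulomb friction
  (mu = 0.02) between all articulating surfaces and between tear faces.
* Tears: longitudinal at the centre of the outer (red) third, 7 mm stable /
  14 mm unstable; radial from the inner rim over 1/6 (stable) or 1/2
  (unstable) of the rim width; both full thickness.
* Hoop stress is read as the maximum principal stress (max PCS); cartilage
  contact is reported through the minimum principal stress.

The methods vignette (`vignettes/meniscal-tear-mechanics.Rmd`) documents
the geometry generator, the solver, every numerical default and the known
limitations.

## Worked example

```r
library(kneefem)

## intact knee, one body weight, full extension
km  <- knee_model(resolution = mesh_resolution(30, 12, 2, 8, 2),
                  loadcase = load_case(flexion_angle = 0, axial_load = 750),
                  penalty_tangent = 2)
sol <- fe_solve(km)
summary(sol)

## a stable longitudinal tear in the medial midsection, warm-started
kt   <- knee_model(loadcase = load_case(0, 750), penalty_tangent = 2,
                   tear = tear_spec("longitudinal", "MM", "middle", "stable"),
                   base = km)
solt <- fe_solve(kt, warm_from = sol)
tear_surface_difference(solt, kt$tear$topology)
```

The intact summary prints (abridged):

```
Knee solution at 0 deg flexion, 750 N axial load (converged)
  vertical tibial reaction: -750.86 N
  max penetration: 0.0157 mm; residual 1.05
  compartment contact:
    side peak_compressive_stress contact_area
  medial                    4.33         1368
 lateral                    1.71          862
  peak meniscal hoop stress (max PCS): MM 5.90 MPa, LM 11.93 MPa
  ligament spring forces (N):
    medial_anterior       18.58
    medial_posterior      19.58
    lateral_anterior      42.38
    lateral_posterior     40.45
```

i.e. the tibia carries the full 750 N (equilibrium to the solver
tolerance), both compartments share load, cartilage peak compression is a
few MPa, the menisci are in hoop tension and all four insertional
ligaments are in tension. The tear report prints:

```
Longitudinal tear surfaces (MM middle, stable, 0 deg): inner -0.887 MPa,
outer -0.791 MPa, difference +0.096 MPa -> favourable
```

a *favourable* difference: the fiber-direction stress on the outer face
exceeds that on the inner face (here both faces sit in the locally
compressed zone under the condyle), so the tear surfaces are pressed
together. The full experiment
matrix (both menisci x three regions x both tear types x both stabilities
x 0/20/30 degrees) runs with `tear_matrix_study()` or, file-based, with
`run_pipeline()`; a thin command-line wrapper is installed as
`exec/kneefem` with subcommands `generate`, `mesh`, `tear`, `solve`,
`post`, `run-all` and `verify`.

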