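---
title: "Modelling myofascial force transmission with a linked fiber-matrix mesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling myofascial force transmission with a linked fiber-matrix mesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Skeletal muscle does not transmit force through its tendons alone.  The
extracellular matrix (ECM) around the fibers is continuous with
neurovascular tracts, intermuscular septa and the epimysia of neighbouring
muscles, so forces also enter and leave the muscle belly along its length.
`lfmmuscle` implements a finite-element model built to study the
consequence of those *epimuscular myofascial loads*: local fiber-direction
strains that can oppose the globally imposed length change — shortened
regions inside a passively lengthened muscle, lengthened regions inside an
isometrically contracting one.

# The model

## Two linked domains

Muscle tissue is treated as two superimposed continua occupying the same
space: an **ECM mesh** of eight-node hexahedra carrying the connective
tissue response, and a coincident **myofiber mesh** carrying the
intracellular (contractile and titin) response.  The two meshes share
nodes only at the myotendinous attachment planes, where both insert into
single layers of aponeurosis elements.  Everywhere else the meshes are
tied by uniaxial elastic links of zero initial length, one per coincident
interior node pair, representing the trans-sarcolemmal attachment
complexes.  With the default 3-elements-in-series x 16-fascicles topology
this yields 48 + 48 muscle elements and 34 links on each of the two model
surfaces.

All element kernels use a total-Lagrangian large-deformation formulation:
the second Piola-Kirchhoff stress is the derivative of a strain-energy
density with respect to the Green-Lagrange strain, evaluated in a local
frame whose axes are the cross-fiber (1), fiber (2) and thickness (3)
directions of each element.

## Constitutive laws

**ECM.**  Each of the six independent local strain components contributes
an exponential component energy $k\,(e^{a_{ij}\varepsilon_{ij}} -
a_{ij}\varepsilon_{ij})$, with the fitted constants $k = 0.05$, $a_{11} =
a_{33} = 8$, $a_{22} = 6$, $a_{12} = a_{23} = a_{31} = 6$.  Normal
components keep this non-symmetric form for strains of either sign (stiff
in tension, soft in compression); for shear the energy is taken even in
the strain so that the shear stress is an odd function — the printed
negative-strain branch of the energy would instead make the shear stress
sign-insensitive, which contradicts the symmetric shear response the
formulation is meant to have.  Incompressibility is imposed by a two-part
penalty $S_s (I_3 - 1)^2 + S_f (\bar I_3 - 1)^2$ ($S_s = 5$, $S_f = 20$)
on the third invariant of the right Cauchy-Green tensor — the model's
local volume ratio — and its quadrature-weighted element mean: the solid
structures conserve volume point-wise, the intracellular fluid only per
element.  A single element stretched 45% along the fiber keeps its local
volume ratio within a fraction of a percent of unity under these weights.

**Myofibers.**  The intracellular stress acts along the local fiber
direction exclusively and is the sum of the active contractile stress
$b_3 e^{b_2\varepsilon^2}$ (lengthening) / $b_3 e^{b_1\varepsilon^3}$
(shortening), scaled to unity at optimum length, and the parabolic titin
tension $t_1\varepsilon^2 + t_2\varepsilon + t_3$ for positive strain.
Two details deserve note:

* *Titin clamp.*  As printed the parabola equals $t_3 = -0.002$ at zero
  strain, which would leave the passive reference state slightly
  pre-stressed and an isometric passive muscle slightly strained.  Since
  zero strain is defined as the undeformed sarcomere state of the passive
  muscle, the default clamps the titin term at zero from below
  (`fiber_params(clamp_titin = )`); the formula as printed is available
  with `clamp = FALSE`.
* *Stress measure.*  The fiber stress is a Cauchy stress along the
  current fiber direction.  By default it is pulled back to a local
  uniaxial second Piola-Kirchhoff stress, $S_{22} = J\sigma/\lambda_f^2$,
  so that one stress measure is integrated throughout
  (`material_set(fiber_stress_mode = "cauchy_pullback")`).  The
  alternative `"pk2_direct"` treats it directly as local PK2; that
  variant is exactly hyperelastic (the 1D stress integrates to a
  potential, `fiber_stress_potential()`) and is the configuration used
  when testing the force-equals-energy-gradient property of the myofiber
  family.

**Aponeuroses.**  A two-parameter Mooney-Rivlin law in reduced
invariants, with bulk modulus derived from the Poisson ratio.  The
constants are not part of the fitted material set and had to be chosen
here.  A first choice based on the tissue-modulus ratio of aponeurosis to
maximal muscle stress (~10^3 in normalized units) makes the thin
aponeurosis layers effectively rigid at this structural geometry: a
fixed-end, fully activated muscle then shortens its fascicles by under
1%, whereas real muscle shortens fascicles by roughly 5-15% in fixed-end
contractions through myotendinous series compliance.  The defaults
(`a10 = 20`, `a01 = 5`, `poisson = 0.3`, small-strain modulus about 130,
~70x the passive fiber-direction tangent of the muscle tissue) were
therefore calibrated once against that physiological anchor.  The
trade-off this hides is discussed under *Limitations*.

## Geometry

Rather than digitizing an anatomical image, `build_muscle_mesh()`
generates a parameterized stand-in for an EDL muscle-belly slice: a
unipennate quadrilateral belly with the proximal aponeurosis along the
upper contour and the distal one along the lower, extruded one element
through the thickness.  Defaults (28.7 mm muscle length, 9.4 mm axial
fascicle span, 2.2 mm belly height, 3 mm slice thickness, a gentle
mid-belly bulge and proximo-distal asymmetry) give fascicle lengths of
~9.7 mm — about one third of muscle length — and a pennation angle of
~13 degrees, consistent with rat EDL architecture.  Aponeurosis layers
triple in thickness toward their tendon ends.  Every geometric quantity
is overridable through `geometry_params()` or the YAML/JSON config.

## Connections to the surroundings

* *Extramuscular*: one grounded spring per fascicle interface, attached
  to the matrix mesh at one third of the fascicle length from its
  proximal end, anchored at the node's reference position (zero initial
  length and force).  The seven most proximal links — the neurovascular
  tract — are stiff (0.25 unit force/mm), the rest compliant (0.033).
* *Intermuscular*: for the epimuscular pair, a second identical muscle is
  placed with its medial face coincident with the target's; all 68
  corresponding medial matrix nodes are linked (0.2 unit force/mm), and
  each muscle keeps its own lateral extramuscular links.
* *Fiber-matrix*: near-rigid ties (default 100x the stiff extramuscular
  value); doubling this stiffness changes the strain fields by well under
  a percent, so results do not hinge on the exact value.

## Protocols

Three cases, each solvable for the isolated, extramuscular and
epimuscular variants (`run_case()`):

* **Case I** — passive, both tendon ends of the target displaced 2 mm
  distally: pure muscle relative position change at constant length.
* **Case II** — Case I followed by a further 2 mm distal displacement of
  the distal end: passive lengthening to 30.7 mm.
* **Case III** — Case I followed by ramping activation to 1 at constant
  length: active isometric contraction.

The synergist of the epimuscular pair keeps its ends fixed throughout; in
Case III it is activated together with the target by default
(`synergist_activated`), since the protocol activates all muscles, and
the reported target-side quantities are robust to this choice.  The
position shift is applied passively before activation.

## Solver

Static equilibria are found by an incremental Newton-Raphson scheme:
displacement phases in 4 equal steps, activation in 10 equal increments
(both configurable).  Each step starts from a displacement-driven
predictor — the linearized response to the prescribed increment about the
converged previous state — which avoids the severely distorted trial
states that plain Newton would produce behind a moving boundary.
Convergence is force-based: the residual norm on the free DOFs must fall
below 0.5% of the internal force norm, with a unit-force floor guarding
the zero-load case.  After the final step converges, a few extra
iterations are allowed while they still reduce the residual sharply, so
reported equilibria are resolved to near machine precision rather than to
the stopping tolerance (visible in the zero-strain baseline, which comes
out at 1e-14 rather than 1e-3).  Non-converging steps are bisected.  The
tangent is assembled by central finite differencing of each element's
internal force (exact spring tangents are analytic); at ~10^3 DOFs the
cost is irrelevant and this eliminates hand-derived consistent-tangent
errors for the exotic material laws.  Linear systems use a direct sparse
factorization.

## Post-processing

`fiber_strain_report()` samples the fiber-direction Green-Lagrange strain
of the *fiber* mesh on the 2 faces x 4 section planes x 17 interfaces
grid: Gauss-point strains are extrapolated to element corners with the
standard trilinear factors and averaged over the elements adjacent to
each sampling node (per-section extrema are mildly sensitive to the
choice of nodal recovery scheme).
`myofascial_load_report()` projects each epimuscular link force onto the
fiber direction at its attachment interface and normalizes all three
cases of a variant by the single largest magnitude.
`proximo_distal_balance()` verifies that the proximo-distal tendon force
difference equals the net axial myofascial load.

# Verification

The test suite is built around independent oracles rather than stored
reference outputs:

* every stress routine matches the finite-difference gradient of its
  energy (1e-6), element forces match finite differences of element
  energies, and the assembled tangent matches the finite-difference
  residual (1e-5), on randomized states under fixed seeds;
* a single element under prescribed affine stretch reproduces a
  closed-form nodal reaction computed from the constitutive formulas
  alone;
* converged states satisfy global equilibrium closure, rigid-body
  objectivity, and invariance to halving the load-step size;
* the sign structure of the three cases is checked across all variants,
  and the stiffness sweep must reduce exactly to the isolated model at
  factor 0 and amplify the opposing strains at factor 2.

Problem sizes in the tests are the model's own: the full 48+48-element
muscle for scenario-level checks, 2x2 to 3x4 element meshes for
property checks on randomized states.

# What the generator does and does not emulate

The parameterized geometry reproduces the topology, dimensions, link
layout and architecture class of a rat-EDL-like unipennate belly
(fascicle length ~ L/3, small pennation), but it is a stand-in, not a
digitized anatomical contour.  Strain *patterns* — signs, proximo-distal
gradients, amplification with connection stiffness — are robust to the
contour; strain *amplitudes* are not, and should be read as
model-specific rather than anatomical.  Two consequences are worth
stating plainly:

* In passive lengthening the compliant aponeuroses absorb part of the
  imposed length change, so fascicle strain peaks (~15-30% depending on
  section) vary by tens of percent relative with the aponeurosis
  constants.
* In active isometric contraction the default model shortens fascicles
  by ~3.5% on average — below the ~10% that fixed-end muscle physiology
  would suggest — and small locally lengthened pockets (~+2%) survive
  near the tendon-end attachments.  Under this contour no aponeurosis
  stiffness removes both shortfalls at once: stiffer aponeuroses give an
  all-shortening field but collapse the mean toward zero, softer ones
  raise the mean but grow the pockets.  The controlling quantity the
  stand-in lacks is pennation gearing (the height-to-span ratio of the
  belly), which lets fascicles shorten by rotating without stretching
  the aponeuroses axially.

Passing tests therefore demonstrate the mechanism — myofascial loads
creating strains that locally oppose the imposed condition — and the
correctness of the numerics, not anatomical strain magnitudes.

# Numerical choices and degenerate inputs

Quadrature is 2x2x2 Gauss per hexahedron; the element-mean volume ratio
uses these weights.  Finite-difference steps are 1e-6 mm (element
tangents).  Element inversion (non-positive volume ratio) raises an
invalid-state error, which the solver treats as a failed step and
bisects.  Meshes with `n_series = 1` have no interior fiber nodes and
hence no fiber-matrix links — the formulas degrade gracefully.  A
configuration whose boundary conditions leave rigid-body modes
unconstrained fails with a singular-tangent diagnostic rather than
returning noise.  All CSV strain outputs are percentages rounded to 0.1
to match the reporting precision of the strain grids; in-memory reports
keep full precision.

# Limitations

Beyond the geometry approximation discussed above: no force-velocity
behaviour (the analyses are static), no viscoelasticity or history
dependence, maximal or zero activation only, one element through the
slice thickness, and an epimuscular neighbourhood reduced to a single
identical synergist.  The YAML configuration was chosen over TOML for the
config surface because a parser for it ships with the package's
dependency set; JSON is accepted interchangeably.
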