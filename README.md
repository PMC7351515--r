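# lfmmuscle

Finite-element modelling of skeletal muscle as two mechanically linked
domains — a **linked fiber-matrix mesh**: an activatable myofiber mesh and
an extracellular-matrix (ECM) mesh occupying the same space, tied by
elastic trans-sarcolemmal links and inserting into hyperelastic
aponeurosis layers.  The package exists to study **epimuscular myofascial
force transmission**: when a muscle is connected to its surroundings
(neurovascular tract, bone, a neighbouring muscle) by elastic links,
changes of the muscle's *position* relative to those surroundings create
myofascial loads that can locally reverse the strain imposed globally —
shortened regions inside a passively lengthened muscle, lengthened regions
inside an isometrically contracting one.

It is intended for muscle biomechanists who want a transparent, fully
scriptable implementation of this model class: every constitutive law,
link, and boundary protocol is plain R, verified against
finite-difference and closed-form oracles.

## The model in brief

* Total-Lagrangian, eight-node hexahedral elements, 2x2x2 Gauss points;
  stress from strain energy, `S = dW/dE` (second Piola-Kirchhoff /
  Green-Lagrange).
* ECM: anisotropic exponential component energies
  `k (exp(a_ij e_ij) - a_ij e_ij)` in the local cross-fiber / fiber /
  thickness frame, plus a two-part incompressibility penalty
  `Ss (I3 - 1)^2 + Sf (I3avg - 1)^2`.
* Myofibers: fiber-direction Cauchy stress only — active
  `b3 exp(b2 e^2)` (lengthening) / `b3 exp(b1 e^3)` (shortening), unity
  at optimum, plus parabolic titin tension `t1 e^2 + t2 e + t3` for
  positive strain.
* Aponeuroses: two-parameter Mooney-Rivlin with derived bulk modulus.
* Spring links: fiber-matrix (near-rigid), extramuscular to ground
  (0.25 / 0.033 unit force/mm, the seven most proximal stiff), and
  intermuscular between two muscles (0.2 unit force/mm).
* Incremental Newton-Raphson with displacement predictor, force-based
  0.5% convergence criterion, and final-step polishing.

Three boundary-condition cases (passive position shift, passive
lengthening, active isometric contraction) cross three model variants
(isolated, extramuscularly connected, epimuscularly connected pair).

## Worked example

Passive lengthening of an extramuscularly connected muscle (Case II):
both tendon ends are first shifted 2 mm distally, then the distal end is
moved 2 mm further, so the muscle is lengthened to 30.7 mm while its
myofascial links are stretched.

```r
library(lfmmuscle)

sol <- run_case(scenario_spec("extramuscular", case = 2))
rep <- fiber_strain_report(sol)
print(rep)
#> fiber-direction strain grid (target muscle): 136 cells
#>   section     min   max  mean
#> 1       I -0.0458 0.170 0.077
#> 2      II  0.0386 0.145 0.096
#> 3     III  0.0755 0.165 0.115
#> 4      IV  0.0794 0.208 0.114
```

Although the muscle as a whole is *lengthened*, fascicle section I (the
proximal ends of the fascicles) contains *shortened* regions — strains
down to about -4.6% — because the extramuscular links, stretched by the
distally imposed position change, pull the proximal fascicle ends
proximally.  Sections III-IV lengthen more than the isolated muscle
would.  The responsible loads:

```r
loads <- myofascial_load_report(list(
  I   = run_case(scenario_spec("extramuscular", 1)),
  II  = sol,
  III = run_case(scenario_spec("extramuscular", 3))))
attr(loads, "normalization")   # largest fiber-direction link force
#> [1] 0.5704069
all(loads$direction == "proximal")
#> [1] TRUE
```

All epimuscular loads on the distally shifted muscle point proximally,
and the largest one (the normalization constant, 1.0 after scaling)
occurs in Case II.  `proximo_distal_balance(sol)` confirms that the
proximal-distal tendon force difference equals the net axial myofascial
load to machine precision.

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lfmmuscle.R", package = "lfmmuscle"))')" \
  run --model extra --case 2 --out out/
```

with YAML/JSON configuration for every parameter block
(`load_config()`).

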