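Package: lfmmuscle
Title: Linked Fiber-Matrix Mesh Finite-Element Modelling of Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear finite-element modelling of skeletal muscle as two
    mechanically linked domains: an activatable myofiber mesh and an
    extracellular-matrix (ECM) mesh occupying the same space, tied by elastic
    trans-sarcolemmal links and inserting into hyperelastic aponeurosis
    layers.  Builds parameterized unipennate muscle geometries resembling the
    rat extensor digitorum longus, attaches extramuscular (muscle-to-ground)
    and intermuscular (muscle-to-muscle) spring connections, and solves
    static large-deformation equilibria with a total-Lagrangian eight-node
    hexahedral formulation and an incremental Newton-Raphson solver.
    Includes scenario protocols for passive repositioning, passive
    lengthening and active isometric contraction, and post-processing of
    fiber-direction strain distributions and epimuscular myofascial loads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
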