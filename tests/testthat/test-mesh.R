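# Geometry and topology of the dual-mesh muscle model.

test_that("default mesh reproduces the stated topology", {
  m <- build_muscle_mesh()
  expect_equal(nrow(m$families$ecm), 48)
  expect_equal(nrow(m$families$myofiber), 48)
  expect_equal(m$n_parallel + 1L, 17L)     # fascicle interfaces
  expect_equal(m$n_series + 1L, 4L)        # fascicle sections
  expect_equal(muscle_length(m), 28.7)
  expect_equal(dim(m$fascicle_grid$lateral), c(4L, 17L))
})

test_that("topology formulas hold for arbitrary mesh sizes", {
  for (ns in c(1L, 2L, 3L, 4L)) for (np in c(1L, 4L, 7L)) {
    m <- build_muscle_mesh(geometry_params(n_series = ns,
                                           n_parallel = np))
    expect_equal(nrow(m$families$ecm), ns * np)
    expect_equal(nrow(m$families$myofiber), ns * np)
    expect_equal(nrow(m$families$aponeurosis), 2L * np)
    ml <- add_fiber_matrix_links(m)
    expect_equal(sum(ml$links$kind == "fiber_matrix"),
                 2L * (ns - 1L) * (np + 1L))
  }
})

test_that("dual meshes share nodes only at myotendinous junctions", {
  m <- build_muscle_mesh()
  mat <- m$maps$mat_id; fib <- m$maps$fib_id
  ns <- m$n_series
  expect_identical(mat[, 1, ], fib[, 1, ])          # proximal attachments
  expect_identical(mat[, ns + 1, ], fib[, ns + 1, ])
  expect_true(all(mat[, 2:ns, ] != fib[, 2:ns, ]))  # interior duplicated
  # duplicated interior nodes are coincident in the reference state
  expect_equal(m$nodes[mat[, 2:ns, ], ], m$nodes[fib[, 2:ns, ], ])
})

test_that("fiber-matrix links: one per interior pair, 34 per face", {
  m <- add_fiber_matrix_links(build_muscle_mesh())
  fm <- m$links[m$links$kind == "fiber_matrix", ]
  expect_equal(nrow(fm), 68)
  z <- m$nodes[fm$node_a, 3]
  expect_equal(as.integer(table(z)), c(34L, 34L))
  # zero reference elongation for every link
  lf <- link_forces(m)
  expect_equal(max(abs(lf$elongation)), 0)
  expect_equal(max(abs(c(lf$fx, lf$fy, lf$fz))), 0)
})

test_that("extramuscular attachment: 17 grounded links, 7 stiff", {
  lp <- link_params()
  m <- attach_extramuscular(add_fiber_matrix_links(build_muscle_mesh()),
                            lp)
  ex <- m$links[m$links$kind == "extramuscular", ]
  expect_equal(nrow(ex), 17)
  expect_equal(sum(ex$stiffness == lp$k_extra_stiff), 7)
  expect_equal(sum(ex$stiffness == lp$k_extra_compliant), 10)
  # the stiff links are the most proximal ones
  expect_true(max(m$nodes[ex$node_a[ex$stiffness == 0.25], 1]) <
                min(m$nodes[ex$node_a[ex$stiffness == 0.033], 1]))
  # anchors coincide with nodes: zero force in the reference state
  expect_equal(max(abs(link_forces(m)$elongation)), 0)
  # degenerate configuration: no stiff links at all
  m0 <- attach_extramuscular(build_muscle_mesh(),
                             link_params(n_stiff_proximal = 0))
  expect_equal(sum(m0$links$stiffness == 0.033), 17)
})

test_that("epimuscular pair links medial faces and grounds lateral ones", {
  pair <- build_epimuscular_pair()
  inter <- pair$links[pair$links$kind == "intermuscular", ]
  expect_equal(nrow(inter), 68)        # 4 section planes x 17 interfaces
  expect_equal(max(abs(pair$nodes[inter$node_a, ] -
                         pair$nodes[inter$node_b, ])), 0)
  ex <- pair$links[pair$links$kind == "extramuscular", ]
  expect_equal(as.integer(table(ex$muscle)), c(17L, 17L))
  # target grounded on z = 0, synergist on the outer face
  expect_true(all(pair$nodes[ex$node_a[ex$muscle == "target"], 3] == 0))
  zs <- pair$nodes[ex$node_a[ex$muscle == "synergist"], 3]
  expect_true(all(zs == max(pair$nodes[, 3])))
  expect_equal(max(abs(link_forces(pair)$elongation)), 0)
})

test_that("local frames are orthonormal and pennate", {
  m <- build_muscle_mesh()
  for (f in names(m$frames)) {
    fr <- m$frames[[f]]
    for (e in seq_len(dim(fr)[3])) {
      R <- fr[, , e]
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
      expect_gt(det(R), 0)
    }
  }
  # fibers make a nonzero angle with the long axis (unipennate)
  for (e in seq_len(48)) {
    d2 <- local_fiber_frame(m, "myofiber", e)[, 2]
    expect_gt(acos(abs(d2[1])), 0.01)
  }
  # axis-aligned test element with identity triad
  expect_equal(local_fiber_frame(single_element_mesh("ecm",
                                                     frame = diag(3)),
                                 "ecm", 1), diag(3))
  expect_error(local_fiber_frame(m, "ecm", 999), "no such element")
})

test_that("each mesh family is watertight", {
  m <- build_muscle_mesh(small_geometry(3L, 4L))
  for (f in c("ecm", "myofiber", "aponeurosis")) {
    counts <- face_share_counts(m$families[[f]])
    expect_true(all(counts <= 2))
    ns <- if (f == "aponeurosis") 1L else 3L
    n_int <- if (f == "aponeurosis") 2L * (4L - 1L) else
      4L * (ns - 1L) + ns * (4L - 1L)
    expect_equal(sum(counts == 2), n_int)
  }
})

test_that("geometry validation rejects degenerate contours", {
  expect_error(build_muscle_mesh(
    geometry_params(belly_height = 0.3, belly_tilt = -1.5)),
    "degenerate contour")
  expect_error(geometry_params(n_series = 0), ">= 1")
  expect_error(geometry_params(slice_thickness = -1), "positive")
})
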