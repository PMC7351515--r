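# Strain-grid recovery, myofascial load reports and force balances on
# reduced meshes (full-size scenario behaviour is covered by the
# acceptance suite).

# a manufactured solution object around a prescribed displacement field
fake_solution <- function(mesh, u) {
  structure(list(u = u, b3 = 0, converged = TRUE, residual_ratio = 0,
                 control = solver_control(), mesh = mesh,
                 reactions = rep(0, 3 * nrow(mesh$nodes)),
                 prescribed_dofs = integer(0),
                 scenario = scenario_spec("isolated", 1)),
            class = "lfmm_solution")
}

test_that("uniform fiber stretch recovers the exact Green-Lagrange value", {
  # near-zero pennation: fibers run along Y; stretch Y by 10%
  g <- geometry_params(n_series = 3L, n_parallel = 4L,
                       fascicle_span = 1e-6, belly_bulge = 0,
                       belly_tilt = 0)
  mesh <- build_muscle_mesh(g)
  u <- as.numeric(t(cbind(0, 0.1 * mesh$nodes[, 2], 0)))
  rep_ <- fiber_strain_report(fake_solution(mesh, u))
  expect_equal(nrow(rep_), 2L * 4L * 5L)
  expect_equal(rep_$strain, rep((1.1^2 - 1) / 2, nrow(rep_)),
               tolerance = 1e-9)
})

test_that("strain grid is complete, zero at reference, translation-invariant", {
  mesh <- build_muscle_mesh(small_geometry(3L, 4L))
  n <- nrow(mesh$nodes)
  r0 <- fiber_strain_report(fake_solution(mesh, rep(0, 3 * n)))
  expect_equal(nrow(r0), 2 * 4 * 5)
  expect_lt(max(abs(r0$strain)), 1e-12)
  r1 <- fiber_strain_report(fake_solution(mesh, rep(c(2, -1, 0.5), n)))
  expect_lt(max(abs(r1$strain)), 1e-12)
  expect_setequal(unique(r0$section), c("I", "II", "III", "IV"))
})

test_that("unconverged solutions are refused by the reporters", {
  mesh <- build_muscle_mesh(small_geometry())
  sol <- fake_solution(mesh, rep(0, 3 * nrow(mesh$nodes)))
  sol$residual_ratio <- 0.5
  expect_error(fiber_strain_report(sol), "not converged")
  expect_error(proximo_distal_balance(sol), "not converged")
})

test_that("load report: empty for isolated, normalized and idempotent", {
  g <- small_geometry(3L, 4L)
  iso <- run_case(scenario_spec("isolated", 1), g = g)
  lr0 <- myofascial_load_report(list(I = iso))
  expect_equal(nrow(lr0), 0)

  sols <- list(I = run_case(scenario_spec("extramuscular", 1), g = g),
               II = run_case(scenario_spec("extramuscular", 2), g = g))
  lr <- myofascial_load_report(sols)
  expect_true(all(abs(lr$normalized) <= 1))
  expect_equal(max(abs(lr$normalized)), 1)
  # renormalizing changes nothing
  expect_equal(lr$normalized / max(abs(lr$normalized)), lr$normalized)
  # distally shifted target: loads pull back proximally
  expect_true(all(lr$fiber_component > 0))
  expect_true(all(lr$direction == "proximal"))
})

test_that("proximo-distal force difference equals the net myofascial load", {
  g <- small_geometry(3L, 4L)
  iso <- run_case(scenario_spec("isolated", 2), g = g)
  b_iso <- proximo_distal_balance(iso)
  scale <- max(abs(c(b_iso$proximal_reaction, b_iso$distal_reaction)))
  expect_lt(abs(b_iso$difference), 0.005 * scale)

  ext <- run_case(scenario_spec("extramuscular", 2), g = g)
  b <- proximo_distal_balance(ext)
  expect_lt(abs(b$closure),
            0.005 * max(abs(c(b$proximal_reaction, b$distal_reaction))))
  expect_gt(abs(b$net_link_axial), 0.01)   # loads actually present
})
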