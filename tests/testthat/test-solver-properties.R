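# Global properties of converged solutions on reduced meshes: objectivity,
# load-step invariance, equilibrium closure.

test_that("solutions are invariant to halving the load-step size", {
  g <- small_geometry(3L, 4L)
  spec <- scenario_spec("isolated", 3)
  s_coarse <- run_case(spec, g = g, steps_disp = 2L, steps_act = 5L)
  s_fine <- run_case(spec, g = g, steps_disp = 4L, steps_act = 10L)
  r1 <- fiber_strain_report(s_coarse)$strain
  r2 <- fiber_strain_report(s_fine)$strain
  expect_lt(max(abs(r1 - r2)), 1e-3 * max(1e-3, max(abs(r2))))
})

test_that("superposed rigid translation leaves strains and elongations unchanged", {
  g <- small_geometry(3L, 4L)
  sol <- run_case(scenario_spec("isolated", 2), g = g)
  mesh <- sol$mesh
  fam <- lfmmuscle:::family_precompute(mesh, "myofiber")
  e0 <- lfmmuscle:::family_fiber_strain(fam, sol$u)
  l0 <- link_forces(mesh, sol$u)$elongation
  shift <- rep(c(-3, 4, 1.5), nrow(mesh$nodes))
  e1 <- lfmmuscle:::family_fiber_strain(fam, sol$u + shift)
  l1 <- link_forces(mesh, sol$u + shift)$elongation
  expect_lt(max(abs(e1 - e0)), 1e-12)
  expect_lt(max(abs(l1 - l0)), 1e-12)
})

test_that("reactions and ground-anchor forces close per axis at equilibrium", {
  g <- small_geometry(3L, 4L)
  sol <- run_case(scenario_spec("extramuscular", 2), g = g)
  lf <- link_forces(sol$mesh, sol$u)
  grounded <- is.na(lf$node_b)
  ground_sum <- colSums(cbind(lf$fx, lf$fy, lf$fz)[grounded, ,
                                                   drop = FALSE])
  react <- matrix(sol$reactions, ncol = 3, byrow = TRUE)
  react_sum <- colSums(react[unique((sol$prescribed_dofs - 1L) %/% 3L) +
                               1L, , drop = FALSE])
  scale <- max(abs(sol$reactions), 1)
  expect_lt(max(abs(react_sum + ground_sum)), 0.005 * scale)
})

test_that("the convergence tolerance is honoured and polishing tightens it", {
  g <- small_geometry(2L, 2L)
  sol <- run_case(scenario_spec("isolated", 2), g = g)
  expect_true(sol$converged)
  expect_lt(sol$residual_ratio, sol$control$tol)
  # the polished final step sits far below the stopping tolerance
  expect_lt(sol$residual_ratio, 1e-8)
})
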