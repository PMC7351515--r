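# Element kernels, springs, assembly and the Newton solver.

test_that("Green-Lagrange strain matches closed forms", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  F <- diag(c(1.2, 1, 1))
  expect_equal(green_lagrange(F)[1, 1], (1.44 - 1) / 2)
  Fs <- diag(3); Fs[1, 2] <- 0.1        # simple shear, gamma = 0.1
  E <- green_lagrange(Fs)
  expect_equal(E[1, 2], 0.05)
  expect_equal(E[2, 2], 0.005)
  expect_error(green_lagrange(diag(2)), "3x3")
})

test_that("element internal force is the gradient of element energy", {
  set.seed(31)
  X <- single_element_mesh("ecm")$nodes
  cases <- list(list(family = "ecm", mats = material_set(), b3 = 0),
                list(family = "aponeurosis", mats = material_set(),
                     b3 = 0),
                list(family = "myofiber",
                     mats = material_set(
                       fiber_stress_mode = "pk2_direct"), b3 = 1))
  for (cs in cases) {
    for (rep in 1:17) {       # ~50 random states across the families
      u <- matrix(runif(24, -0.08, 0.08), 8, 3)
      f <- element_internal_force(X, u, cs$family, cs$mats, b3 = cs$b3)
      h <- 1e-6
      for (d in seq(1, 24, by = 2)) {
        n <- (d - 1) %/% 3 + 1; a <- (d - 1) %% 3 + 1
        up <- u; up[n, a] <- up[n, a] + h
        um <- u; um[n, a] <- um[n, a] - h
        fd <- (element_energy(X, up, cs$family, cs$mats, b3 = cs$b3) -
                 element_energy(X, um, cs$family, cs$mats,
                                b3 = cs$b3)) / (2 * h)
        expect_equal(f[n, a], fd, tolerance = 1e-6)
      }
    }
    # zero displacement, passive reference: no internal force
    f0 <- element_internal_force(X, matrix(0, 8, 3), cs$family, cs$mats,
                                 b3 = 0)
    expect_lt(max(abs(f0)), 1e-12)
  }
})

test_that("activated myofiber element pulls its end faces together", {
  dims <- c(1, 2, 3)
  m <- single_element_mesh("myofiber", dims)      # fiber along global X
  f <- element_internal_force(m$nodes, matrix(0, 8, 3), "myofiber",
                              material_set(), frame = m$frames$myofiber[, , 1],
                              b3 = 1)
  A <- dims[2] * dims[3]                          # fiber cross-section
  fx_min <- sum(f[m$node_sets$xmin, 1])
  fx_max <- sum(f[m$node_sets$xmax, 1])
  expect_equal(abs(fx_min), A, tolerance = 1e-10)
  expect_equal(fx_min, -fx_max)
  # supports must pull outward to hold a tensed fiber: faces attract
  expect_lt(fx_min, 0)
  expect_lt(max(abs(f[, 2:3])), 1e-10)            # fiber direction only
})

test_that("spring forces are linear and uniaxial", {
  s0 <- spring_force(c(0, 0, 0), c(0, 0, 0), k = 5)
  expect_equal(s0$force_a, c(0, 0, 0))
  s1 <- spring_force(c(0, 0, 0), c(1, 0, 0), k = 0.25)
  expect_equal(s1$force_a, c(0.25, 0, 0))
  expect_equal(s1$force_b, -s1$force_a)
  s2 <- spring_force(c(0, 0, 0), c(2, 0, 0), k = 0.25)
  expect_equal(s2$force_a, 2 * s1$force_a)
  # finite reference length: force from elongation along the chord
  s3 <- spring_force(c(0, 0, 0), c(0, 3, 0), k = 2, ref_length = 1)
  expect_equal(s3$force_a, c(0, 4, 0))
  expect_equal(s3$elongation, 2)
})

test_that("assembled tangent matches the finite-difference residual", {
  set.seed(41)
  mesh <- add_fiber_matrix_links(build_muscle_mesh(small_geometry()))
  mats <- material_set()
  u <- runif(3 * nrow(mesh$nodes), -0.02, 0.02)
  sys <- assemble(mesh, u, mats, b3 = 0.4)
  h <- 1e-6
  for (d in sample(seq_along(u), 10)) {
    up <- u; up[d] <- up[d] + h
    um <- u; um[d] <- um[d] - h
    fd <- (lfmmuscle:::internal_force(mesh, up, mats, 0.4) -
             lfmmuscle:::internal_force(mesh, um, mats, 0.4)) / (2 * h)
    expect_equal(as.numeric(sys$K[, d]), fd,
                 tolerance = 1e-5)
  }
})

test_that("rigid translation produces no residual on a floating mesh", {
  mesh <- add_fiber_matrix_links(build_muscle_mesh(small_geometry()))
  u <- rep(c(1.5, -2, 0.7), nrow(mesh$nodes))
  r <- lfmmuscle:::internal_force(mesh, u, material_set(), 0)
  expect_lt(max(abs(r)), 1e-9)
  # action equals reaction: per-axis residual sums vanish in any state
  set.seed(5)
  u2 <- runif(length(u), -0.05, 0.05)
  r2 <- lfmmuscle:::internal_force(mesh, u2, material_set(), 0)
  sums <- colSums(matrix(r2, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(sums)), 1e-9 * max(1, max(abs(r2))))
})

test_that("prescribed affine stretch reproduces the closed-form reaction", {
  # all eight nodes of one ECM element follow a homogeneous deformation;
  # nodal forces then equal P times the exact shape-gradient integrals
  lam <- 1.1
  mats <- material_set()
  mesh <- single_element_mesh("ecm", frame = diag(3))
  Fh <- diag(c(lam, 1, 1))
  X <- mesh$nodes
  u_nodes <- X %*% t(Fh) - X
  bc <- data.frame(dof = seq_len(24),
                   value = as.numeric(t(u_nodes)))
  sol <- newton_solve(mesh, mats, load_phase(bc, n_steps = 2))
  # independent closed form: E = (F'F - I)/2 diagonal, exponential law,
  # uniform-I3 penalty, P = F (S_aniso + S_pen)
  E11 <- (lam^2 - 1) / 2
  p <- mats$ecm
  S <- diag(c(p$k * p$a11 * (exp(p$a11 * E11) - 1), 0, 0))
  I3 <- lam^2
  S <- S + 4 * ((p$Ss + p$Sf) * (I3 - 1)) * I3 *
    diag(1 / c(lam^2, 1, 1))
  P <- Fh %*% S
  corner_sign <- 2 * single_element_mesh("ecm")$nodes - 1
  for (n in 1:8) {
    grad_int <- corner_sign[n, ] / 4    # exact integral of dN/dX over cube
    expect_equal(sol$reactions[3 * (n - 1) + 1:3],
                 as.numeric(P %*% grad_int), tolerance = 1e-9)
  }
})

test_that("solver reports unconstrained systems instead of nonsense", {
  mesh <- add_fiber_matrix_links(build_muscle_mesh(small_geometry()))
  bc <- data.frame(dof = 1L, value = 0.5)   # single DOF cannot hold it
  expect_error(
    newton_solve(mesh, material_set(),
                 load_phase(bc, n_steps = 1),
                 solver_control(max_iter = 3, max_bisect = 0)),
    "singular|converge")
})

test_that("rigid end translation leaves a small isolated mesh unstrained", {
  mesh <- add_fiber_matrix_links(build_muscle_mesh(small_geometry(3L, 4L)))
  tgt <- mesh$muscles$target$node_sets
  bc <- bc_rigid_sets(p = list(nodes = tgt$proximal_end, u = c(2, 0, 0)),
                      d = list(nodes = tgt$distal_end, u = c(2, 0, 0)))
  sol <- newton_solve(mesh, material_set(), load_phase(bc, n_steps = 2))
  fam <- lfmmuscle:::family_precompute(mesh, "myofiber")
  eg <- lfmmuscle:::family_fiber_strain(fam, sol$u)
  expect_lt(max(abs(eg)), 1e-9)
})
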