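# Single-element test rigs: constitutive stress-strain curves and the
# volume-conservation check of the ECM element under large fiber-direction
# stretch.

#' Single-hexahedron mesh
#'
#' A one-element mesh of the given family spanning `[0, dims]`, mainly for
#' unit tests and single-element rigs.  The local fiber direction is the
#' global X axis by default.
#'
#' @param family element family.
#' @param dims edge lengths (mm).
#' @param frame local triad (columns cross-fiber, fiber, thickness); the
#'   default puts the fiber direction along global X.
#' @return A `muscle_mesh` with a single element and no links.
#' @export
single_element_mesh <- function(family = "ecm", dims = c(1, 1, 1),
                                frame = cbind(c(0, -1, 0), c(1, 0, 0),
                                              c(0, 0, 1))) {
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  nodes <- sweep(corners, 2, dims, `*`)
  structure(list(
    nodes = nodes,
    families = setNames(list(matrix(1:8, 1, 8)), family),
    frames = setNames(list(array(frame, dim = c(3, 3, 1))), family),
    act_scale = 1,
    links = empty_links(),
    node_sets = list(
      xmin = which(corners[, 1] == 0), xmax = which(corners[, 1] == 1),
      ymin = which(corners[, 2] == 0), ymax = which(corners[, 2] == 1),
      zmin = which(corners[, 3] == 0), zmax = which(corners[, 3] == 1)),
    muscles = list(), geometry = NULL, n_series = 1L, n_parallel = 1L),
    class = "muscle_mesh")
}

#' ECM element volume-conservation rig
#'
#' Stretches a single ECM element along its fiber direction with symmetry
#' conditions on the lower faces and free lateral expansion, solves the
#' static equilibrium, and reports the maximal relative deviation of the
#' local volume ratio from unity over the Gauss points.  With the default
#' penalty weights the deviation stays small even for length changes well
#' beyond 40%.
#'
#' @param stretch fiber-direction stretch ratio (e.g. 1.45 for a 45%
#'   length change).
#' @param materials [material_set()].
#' @param control [solver_control()].
#' @param n_steps load steps used to reach the stretch.
#' @return List: `max_dev_pct` (max |volume ratio - 1| x 100), `I3` (the
#'   eight Gauss-point third invariants, the model's local volume ratios)
#'   and the `solution`.
#' @export
ecm_volume_test <- function(stretch = 1.45, materials = material_set(),
                            control = solver_control(), n_steps = 6L) {
  mesh <- single_element_mesh("ecm")
  sets <- mesh$node_sets
  bc <- rbind(
    data.frame(dof = 3 * (sets$xmin - 1L) + 1L, value = 0),
    data.frame(dof = 3 * (sets$xmax - 1L) + 1L, value = stretch - 1),
    data.frame(dof = 3 * (sets$ymin - 1L) + 2L, value = 0),
    data.frame(dof = 3 * (sets$zmin - 1L) + 3L, value = 0))
  sol <- newton_solve(mesh, materials,
                      load_phase(bc, b3 = 0, n_steps = n_steps), control)
  fam <- family_precompute(mesh, "ecm")
  xcur <- .family_xcur(fam, sol$u)
  I3 <- vapply(1:8, function(g) .kinematics_gp(fam, xcur, g)$I3[1],
               numeric(1))
  # the model convention takes I3 itself as the local volume ratio, and
  # the penalty weights were tuned against that convention
  list(max_dev_pct = 100 * max(abs(I3 - 1)), I3 = I3,
       volume_ratio = I3, solution = sol)
}

#' Constitutive stress-strain curves
#'
#' Tabulates the material laws over a strain range for plotting or export:
#' ECM normal (fiber, cross-fiber, thickness) and shear stresses, active
#' contractile stress at full activation, and titin stress.
#'
#' @param strain_range range of Green-Lagrange strain.
#' @param n points per curve.
#' @param materials [material_set()].
#' @return Data frame with columns `strain`, `stress`, `component`.
#' @export
material_curves <- function(strain_range = c(-0.5, 0.5), n = 201L,
                            materials = material_set()) {
  eps <- seq(strain_range[1], strain_range[2], length.out = n)
  p <- materials$ecm; fp <- materials$fiber
  rows <- list(
    data.frame(strain = eps, component = "ecm_fiber",
               stress = .sij_normal(eps, p$k, p$a22)),
    data.frame(strain = eps, component = "ecm_cross_fiber",
               stress = .sij_normal(eps, p$k, p$a11)),
    data.frame(strain = eps, component = "ecm_thickness",
               stress = .sij_normal(eps, p$k, p$a33)),
    data.frame(strain = eps, component = "ecm_shear",
               stress = .sij_shear(eps, p$k, p$a12)),
    data.frame(strain = eps, component = "active",
               stress = active_stress(eps, 1, fp)),
    data.frame(strain = eps, component = "titin",
               stress = titin_stress(eps, fp)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("strain", "stress", "component")]
}

#' Quick model verification suite
#'
#' Cheap invariant checks on small randomized systems: orthonormal local
#' frames, zero reference-state residual and link forces, agreement of the
#' single-element internal force with the finite-difference gradient of the
#' element energy, and agreement of the assembled tangent with the
#' finite-difference residual.
#'
#' @param seed RNG seed for the randomized states.
#' @return Named logical vector of check results (all TRUE on success).
#' @export
verify_model <- function(seed = 1L) {
  set.seed(seed)
  g <- geometry_params(n_series = 2L, n_parallel = 2L)
  mesh <- add_fiber_matrix_links(build_muscle_mesh(g))
  mats <- material_set(fiber_stress_mode = "pk2_direct")
  checks <- c(frames_orthonormal = TRUE, reference_equilibrium = TRUE,
              force_energy_gradient = TRUE, tangent_consistency = TRUE)
  for (f in names(mesh$frames)) {
    fr <- mesh$frames[[f]]
    for (e in seq_len(dim(fr)[3]))
      if (max(abs(crossprod(fr[, , e]) - diag(3))) > 1e-12)
        checks["frames_orthonormal"] <- FALSE
  }
  r0 <- internal_force(mesh, rep(0, 3 * nrow(mesh$nodes)), mats, 0)
  if (max(abs(r0)) > 1e-10) checks["reference_equilibrium"] <- FALSE

  X <- single_element_mesh("ecm")$nodes
  for (i in 1:5) {
    u <- matrix(stats::runif(24, -0.05, 0.05), 8, 3)
    f <- element_internal_force(X, u, "ecm", mats)
    h <- 1e-6
    for (d in sample(1:24, 4)) {
      n <- (d - 1) %/% 3 + 1; a <- (d - 1) %% 3 + 1
      up <- u; up[n, a] <- up[n, a] + h
      um <- u; um[n, a] <- um[n, a] - h
      fd <- (element_energy(X, up, "ecm", mats) -
               element_energy(X, um, "ecm", mats)) / (2 * h)
      if (abs(fd - f[n, a]) > 1e-5 * max(1, abs(fd)))
        checks["force_energy_gradient"] <- FALSE
    }
  }

  u <- stats::runif(3 * nrow(mesh$nodes), -0.02, 0.02)
  sys <- assemble(mesh, u, mats, b3 = 0.5)
  h <- 1e-6
  for (d in sample(seq_along(u), 6)) {
    up <- u; up[d] <- up[d] + h
    um <- u; um[d] <- um[d] - h
    fd <- (internal_force(mesh, up, mats, 0.5) -
             internal_force(mesh, um, mats, 0.5)) / (2 * h)
    if (max(abs(fd - sys$K[, d])) > 1e-4 * max(1, max(abs(fd))))
      checks["tangent_consistency"] <- FALSE
  }
  checks
}
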