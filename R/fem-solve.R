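# Incremental Newton-Raphson solver for the static large-deformation
# problem.  Loading is applied in phases (each a set of prescribed end-state
# displacements plus an activation target) subdivided into equal load
# steps; within a step Newton iterates until the force-based convergence
# criterion is met.  Non-converging steps are bisected.

#' Solver control settings
#'
#' @param tol force-based convergence tolerance: a step is converged when
#'   the L2 norm of the residual on the free DOFs falls below
#'   `tol * max(||internal force||, floor)`.
#' @param floor reference-force floor guarding the zero-load case (unit
#'   force).
#' @param max_iter Newton iterations per step before the step is bisected.
#' @param max_bisect maximum step-bisection depth.
#' @param polish after the final step converges, allow a few further
#'   Newton iterations while they still reduce the residual sharply, so
#'   that reported equilibria are resolved well beyond the stopping
#'   tolerance.
#' @param polish_iter cap on polish iterations.
#' @param fd_step finite-difference step (mm) for the element tangents.
#' @return List of class `solver_control`.
#' @export
solver_control <- function(tol = 0.005, floor = 1.0, max_iter = 30L,
                           max_bisect = 5L, polish = TRUE,
                           polish_iter = 8L, fd_step = 1e-6) {
  stopifnot(tol > 0, floor > 0, max_iter >= 1, max_bisect >= 0)
  structure(list(tol = tol, floor = floor, max_iter = as.integer(max_iter),
                 max_bisect = as.integer(max_bisect),
                 polish = isTRUE(polish),
                 polish_iter = as.integer(polish_iter), fd_step = fd_step),
            class = "solver_control")
}

#' Boundary conditions from node sets
#'
#' Builds a prescribed-displacement table: every listed node is prescribed
#' on all three axes at the given displacement vector (rigid-set
#' displacement of tendon end faces).
#'
#' @param ... named arguments: each name is ignored, each value a list
#'   `list(nodes = <ids>, u = c(ux, uy, uz))`.
#' @return Data frame with columns `dof`, `value`.
#' @export
bc_rigid_sets <- function(...) {
  parts <- list(...)
  out <- lapply(parts, function(p) {
    data.frame(dof = as.integer(outer(3 * (p$nodes - 1L), 1:3, `+`)),
               value = rep(p$u, each = length(p$nodes)))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df <- df[!duplicated(df$dof), , drop = FALSE]
  df
}

#' Loading phase
#'
#' One stage of a protocol: end-state prescribed displacements and an
#' activation target, applied in `n_steps` equal increments from the state
#' reached by the previous phase.
#'
#' @param bc prescribed-displacement table from [bc_rigid_sets()].
#' @param b3 activation level at the end of the phase.
#' @param n_steps number of equal load steps.
#' @return List of class `load_phase`.
#' @export
load_phase <- function(bc, b3 = 0, n_steps = 4L) {
  stopifnot(is.data.frame(bc), n_steps >= 1)
  structure(list(bc = bc, b3 = b3, n_steps = as.integer(n_steps)),
            class = "load_phase")
}

# one Newton solve from the current state to fixed prescribed values /
# activation; returns list(u, iterations, res_ratio, converged)
.newton_step <- function(mesh, materials, u, presc_dof, presc_val, b3,
                         ctrl, precomp, final = FALSE) {
  n_dof <- 3 * nrow(mesh$nodes)
  free <- setdiff(seq_len(n_dof), presc_dof)
  # displacement-driven predictor: linearize at the (undistorted) start
  # state and solve for the free-DOF response to the prescribed increment,
  # rather than leaving the interior behind the moving boundary
  pred <- tryCatch({
    sys0 <- assemble(mesh, u, materials, b3, precomp, need_tangent = TRUE)
    dup <- presc_val - u[presc_dof]
    rhs <- -(sys0$residual[free] +
               as.numeric(sys0$K[free, presc_dof, drop = FALSE] %*% dup))
    as.numeric(Matrix::solve(sys0$K[free, free, drop = FALSE], rhs))
  }, error = function(e) NULL)
  u[presc_dof] <- presc_val
  if (!is.null(pred)) {
    u_try <- u
    u_try[free] <- u[free] + pred
    ok <- tryCatch({
      internal_force(mesh, u_try, materials, b3, precomp)
      TRUE
    }, error = function(e) FALSE)
    if (ok) u <- u_try
  }
  res_hist <- numeric(0)
  converged <- FALSE
  it <- 0L
  polishing <- FALSE
  prev_res <- Inf
  repeat {
    sys <- tryCatch(
      assemble(mesh, u, materials, b3, precomp, need_tangent = TRUE),
      error = function(e) e)
    if (inherits(sys, "error")) {
      if (it == 0L) stop(sys)          # even the start state is invalid
      return(list(u = u, iterations = it, res_ratio = Inf,
                  converged = FALSE))
    }
    rf <- sys$residual[free]
    res <- sqrt(sum(rf^2))
    ref <- max(sys$norm_internal, ctrl$floor)
    if (!is.finite(res) || !is.finite(ref)) {
      if (it == 0L)
        stop("non-finite residual at the start state", call. = FALSE)
      return(list(u = u, iterations = it, res_ratio = Inf,
                  converged = FALSE))
    }
    res_hist <- c(res_hist, res)
    if (!polishing && res <= ctrl$tol * ref) {
      converged <- TRUE
      if (!(final && ctrl$polish)) break
      polishing <- TRUE
      polish_left <- ctrl$polish_iter
    }
    if (polishing) {
      if (res <= 1e-12 * ref || polish_left <= 0L ||
          res > 0.5 * prev_res) break
      polish_left <- polish_left - 1L
    } else if (it >= ctrl$max_iter) {
      return(list(u = u, iterations = it, res_ratio = res / ref,
                  converged = FALSE))
    }
    Kff <- sys$K[free, free, drop = FALSE]
    du <- tryCatch(-as.numeric(Matrix::solve(Kff, rf)),
                   error = function(e)
                     stop("singular tangent: free rigid-body modes or ",
                          "unconstrained DOFs remain (",
                          conditionMessage(e), ")", call. = FALSE))
    # backtracking guard against divergence / element inversion
    step <- 1
    repeat {
      u_try <- u
      u_try[free] <- u[free] + step * du
      ok <- tryCatch({
        r_try <- internal_force(mesh, u_try, materials, b3, precomp)
        sqrt(sum(r_try[free]^2))
      }, error = function(e) NA_real_)
      if (!is.na(ok) && (ok < res || step < 0.26)) break
      step <- step / 2
      if (step < 1 / 16) break
    }
    u <- u_try
    prev_res <- res
    it <- it + 1L
  }
  list(u = u, iterations = it, res_ratio = res_hist[length(res_hist)] /
         max(ref, 1e-300), converged = converged)
}

# recursive step with bisection on failure
.solve_increment <- function(mesh, materials, state, presc_dof, val_from,
                             val_to, b3_from, b3_to, ctrl, precomp, depth,
                             final) {
  out <- .newton_step(mesh, materials, state$u, presc_dof, val_to, b3_to,
                      ctrl, precomp, final = final)
  if (out$converged) {
    state$u <- out$u
    state$iters <- c(state$iters, out$iterations)
    state$res_ratio <- out$res_ratio
    return(state)
  }
  if (depth >= ctrl$max_bisect)
    stop("solver failed to converge (residual ratio ",
         signif(out$res_ratio, 3), " after step bisection to depth ",
         depth, ")", call. = FALSE)
  mid_val <- (val_from + val_to) / 2
  mid_b3 <- (b3_from + b3_to) / 2
  state <- .solve_increment(mesh, materials, state, presc_dof, val_from,
                            mid_val, b3_from, mid_b3, ctrl, precomp,
                            depth + 1L, final = FALSE)
  .solve_increment(mesh, materials, state, presc_dof, mid_val, val_to,
                   mid_b3, b3_to, ctrl, precomp, depth + 1L, final = final)
}

#' Incremental Newton-Raphson solve
#'
#' Applies the loading phases in order, each in equal increments of the
#' prescribed displacements and activation, and iterates each step to the
#' force-based convergence criterion.  Reaction forces are recovered from
#' the residual at the prescribed DOFs of the converged state.
#'
#' @param mesh a `muscle_mesh` (with links attached as required).
#' @param materials [material_set()].
#' @param phases list of [load_phase()] objects.
#' @param control [solver_control()].
#' @param u0 optional initial displacement state.
#' @return Object of class `lfmm_solution`: displacements `u`, final
#'   activation `b3`, `converged`, `residual_ratio`, per-step `history`,
#'   `reactions` (full residual vector of the converged state; meaningful
#'   at prescribed DOFs), and the mesh/materials used.
#' @export
newton_solve <- function(mesh, materials = material_set(), phases,
                         control = solver_control(), u0 = NULL) {
  if (inherits(phases, "load_phase")) phases <- list(phases)
  precomp <- mesh_precompute(mesh)
  n_dof <- 3 * nrow(mesh$nodes)
  u <- if (is.null(u0)) numeric(n_dof) else u0
  b3 <- 0
  history <- data.frame()
  n_ph <- length(phases)
  for (pi in seq_len(n_ph)) {
    ph <- phases[[pi]]
    presc_dof <- ph$bc$dof
    val_start <- u[presc_dof]
    val_end <- ph$bc$value
    b3_start <- b3
    for (s in seq_len(ph$n_steps)) {
      f1 <- (s - 1) / ph$n_steps; f2 <- s / ph$n_steps
      final <- (pi == n_ph && s == ph$n_steps)
      state <- list(u = u, iters = integer(0), res_ratio = NA_real_)
      state <- .solve_increment(
        mesh, materials, state, presc_dof,
        val_start + f1 * (val_end - val_start),
        val_start + f2 * (val_end - val_start),
        b3_start + f1 * (ph$b3 - b3_start),
        b3_start + f2 * (ph$b3 - b3_start),
        control, precomp, 0L, final)
      u <- state$u
      history <- rbind(history, data.frame(
        phase = pi, step = s, iterations = sum(state$iters),
        substeps = length(state$iters), residual_ratio = state$res_ratio))
    }
    b3 <- ph$b3
  }
  reactions <- internal_force(mesh, u, materials, b3, precomp)
  presc_all <- unique(unlist(lapply(phases, function(p) p$bc$dof)))
  structure(list(u = u, b3 = b3, converged = TRUE,
                 residual_ratio = history$residual_ratio[nrow(history)],
                 history = history, reactions = reactions,
                 prescribed_dofs = sort(presc_all), mesh = mesh,
                 materials = materials, control = control),
            class = "lfmm_solution")
}

#' @export
print.lfmm_solution <- function(x, ...) {
  cat("lfmm_solution: b3 =", x$b3,
      "| residual ratio", signif(x$residual_ratio, 3),
      "|", nrow(x$history), "load steps,",
      sum(x$history$iterations), "Newton iterations\n")
  invisible(x)
}

# per-Gauss-point local fiber strain (E22) of a family; returns nel x 8
family_fiber_strain <- function(fam, u) {
  xcur <- .family_xcur(fam, u)
  out <- matrix(0, fam$nel, 8)
  for (g in 1:8) {
    kg <- .kinematics_gp(fam, xcur, g)
    E <- (kg$C - outer(rep(1, fam$nel), diag(3))) / 2
    Eloc <- .to_local(fam$R, E)
    out[, g] <- Eloc[, 2, 2]
  }
  out
}
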