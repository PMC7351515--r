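# The three model variants (isolated / extramuscular / epimuscular) crossed
# with the three loading cases:
#   Case I   passive isometric muscle with imposed relative position change
#            (both tendon ends displaced distally, length unchanged),
#   Case II  passive lengthened muscle (Case I, then the distal end is
#            displaced further distally),
#   Case III active isometric muscle with imposed relative position change
#            (Case I, then activation ramped up at constant length).

#' Scenario specification
#'
#' @param model_variant `"isolated"`, `"extramuscular"` or `"epimuscular"`.
#' @param case 1, 2 or 3 (Cases I-III).
#' @param end_shift distal displacement (mm) of both target-muscle tendon
#'   ends: the imposed muscle relative position change.
#' @param extra_lengthening additional distal-end displacement (mm) for
#'   Case II.
#' @param activation_target final activation level for Case III.
#' @param synergist_activated whether the synergist muscle of the
#'   epimuscular pair is also activated in Case III.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(model_variant = c("isolated", "extramuscular",
                                            "epimuscular"),
                          case = 1L, end_shift = 2.0,
                          extra_lengthening = 2.0, activation_target = 1.0,
                          synergist_activated = TRUE) {
  model_variant <- match.arg(model_variant)
  case <- as.integer(case)
  if (!case %in% 1:3) stop("'case' must be 1, 2 or 3", call. = FALSE)
  if (activation_target < 0 || activation_target > 1)
    stop("'activation_target' must lie in [0, 1]", call. = FALSE)
  structure(list(model_variant = model_variant, case = case,
                 end_shift = end_shift,
                 extra_lengthening = extra_lengthening,
                 activation_target = activation_target,
                 synergist_activated = isTRUE(synergist_activated)),
            class = "scenario_spec")
}

#' Build the mesh of a model variant
#'
#' Isolated: the dual-mesh muscle with its fiber-matrix links only.
#' Extramuscular: additionally grounded on the lateral face.  Epimuscular:
#' two muscles interlinked medially, each grounded laterally.
#'
#' @param variant model variant name.
#' @param g [geometry_params()].
#' @param lp [link_params()].
#' @return A `muscle_mesh`.
#' @export
build_model <- function(variant = c("isolated", "extramuscular",
                                    "epimuscular"),
                        g = geometry_params(), lp = link_params()) {
  variant <- match.arg(variant)
  if (variant == "epimuscular") return(build_epimuscular_pair(g, lp))
  mesh <- add_fiber_matrix_links(build_muscle_mesh(g), lp)
  if (variant == "extramuscular")
    mesh <- attach_extramuscular(mesh, lp, "lateral")
  mesh
}

#' Run one scenario
#'
#' Builds the model variant, assembles the loading phases of the requested
#' case and solves them incrementally.  For the epimuscular variant the
#' synergist's tendon ends are held at their reference positions
#' throughout.
#'
#' @param spec [scenario_spec()].
#' @param g [geometry_params()].
#' @param lp [link_params()].
#' @param materials [material_set()].
#' @param control [solver_control()].
#' @param steps_disp load steps per displacement phase.
#' @param steps_act load steps for the activation ramp.
#' @param mesh optionally a pre-built mesh (must match the variant), e.g.
#'   from [build_model()] with modified link stiffnesses.
#' @return An `lfmm_solution` with the scenario attached as `$scenario`.
#' @export
run_case <- function(spec, g = geometry_params(), lp = link_params(),
                     materials = material_set(),
                     control = solver_control(), steps_disp = 4L,
                     steps_act = 10L, mesh = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(mesh)) mesh <- build_model(spec$model_variant, g, lp)
  if (spec$model_variant == "epimuscular" && spec$case == 3L &&
      !spec$synergist_activated)
    mesh$act_scale[mesh$myofiber_muscle == "synergist"] <- 0

  tgt <- mesh$muscles$target$node_sets
  shift <- c(spec$end_shift, 0, 0)
  fix_syn <- list()
  if (spec$model_variant == "epimuscular") {
    syn <- mesh$muscles$synergist$node_sets
    fix_syn <- list(sp = list(nodes = syn$proximal_end, u = c(0, 0, 0)),
                    sd = list(nodes = syn$distal_end, u = c(0, 0, 0)))
  }
  bc_shift <- do.call(bc_rigid_sets, c(
    list(p = list(nodes = tgt$proximal_end, u = shift),
         d = list(nodes = tgt$distal_end, u = shift)), fix_syn))

  phases <- list(load_phase(bc_shift, b3 = 0, n_steps = steps_disp))
  if (spec$case == 2L) {
    bc_len <- do.call(bc_rigid_sets, c(
      list(p = list(nodes = tgt$proximal_end, u = shift),
           d = list(nodes = tgt$distal_end,
                    u = shift + c(spec$extra_lengthening, 0, 0))),
      fix_syn))
    phases <- c(phases, list(load_phase(bc_len, b3 = 0,
                                        n_steps = steps_disp)))
  } else if (spec$case == 3L) {
    phases <- c(phases, list(load_phase(bc_shift,
                                        b3 = spec$activation_target,
                                        n_steps = steps_act)))
  }
  sol <- newton_solve(mesh, materials, phases, control)
  sol$scenario <- spec
  sol
}

#' Rerun a scenario over scaled epimuscular link stiffnesses
#'
#' Scales all extramuscular and intermuscular link stiffnesses by each
#' factor (fiber-matrix links are untouched) and re-solves the scenario.
#' Factor 0 disconnects the muscle from its surroundings and reproduces
#' the isolated-model strain field.
#'
#' @param spec [scenario_spec()] using a connected variant.
#' @param factors numeric vector of stiffness scale factors (>= 0).
#' @inheritParams run_case
#' @return Named list of `lfmm_solution` objects, one per factor.
#' @export
stiffness_sweep <- function(spec, factors, g = geometry_params(),
                            lp = link_params(),
                            materials = material_set(),
                            control = solver_control(), steps_disp = 4L,
                            steps_act = 10L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$model_variant == "isolated")
    stop("stiffness_sweep requires a connected model variant",
         call. = FALSE)
  if (any(factors < 0)) stop("factors must be >= 0", call. = FALSE)
  base <- build_model(spec$model_variant, g, lp)
  out <- lapply(factors, function(f) {
    mesh <- base
    epi <- mesh$links$kind %in% c("extramuscular", "intermuscular")
    mesh$links$stiffness[epi] <- mesh$links$stiffness[epi] * f
    if (f == 0) mesh$links <- mesh$links[!epi, , drop = FALSE]
    run_case(spec, g, lp, materials, control, steps_disp, steps_act,
             mesh = mesh)
  })
  names(out) <- paste0("factor_", factors)
  out
}
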