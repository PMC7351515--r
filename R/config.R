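# Configuration: a nested list mirroring the parameter constructors, read
# from YAML (primary) or JSON, merged over the model defaults, validated
# through the constructors, and echoed to the output directory for
# provenance.

.default_config <- function() {
  list(geometry = unclass(geometry_params()),
       materials = list(ecm = unclass(ecm_params()),
                        fiber = unclass(fiber_params()),
                        apon = unclass(apon_params())[c("a10", "a01",
                                                        "poisson")],
                        fiber_stress_mode = "cauchy_pullback"),
       links = unclass(link_params()),
       solver = unclass(solver_control()),
       scenario = unclass(scenario_spec()),
       steps = list(displacement = 4L, activation = 10L),
       output_dir = "lfmm_out",
       seed = 1L)
}

.merge_config <- function(defaults, override, path = "", problems) {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      problems$msgs <- c(problems$msgs, paste0("unknown key '", key, "'"))
      next
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(override[[nm]])) {
        problems$msgs <- c(problems$msgs,
                           paste0("'", key, "' must be a block"))
        next
      }
      defaults[[nm]] <- .merge_config(defaults[[nm]], override[[nm]], key,
                                      problems)
    } else {
      v <- override[[nm]]
      d <- defaults[[nm]]
      if (is.numeric(d) && !is.numeric(v) ||
          is.character(d) && !is.character(v) ||
          is.logical(d) && !is.logical(v)) {
        problems$msgs <- c(problems$msgs,
                           paste0("type mismatch for '", key, "'"))
        next
      }
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration file, merges it
#' over the full model defaults, and validates every block through the
#' parameter constructors.  An empty file yields the complete default
#' configuration.  All problems (unknown keys, type mismatches, invariant
#' violations) are reported together.
#'
#' @param path configuration file, or NULL for pure defaults.
#' @return Object of class `lfmm_config`: a validated nested list with
#'   resolved parameter objects under `$params`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    override <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(override)) override <- list()
    problems <- new.env()
    problems$msgs <- character(0)
    cfg <- .merge_config(cfg, override, "", problems)
    if (length(problems$msgs))
      stop("invalid configuration:\n  - ",
           paste(problems$msgs, collapse = "\n  - "), call. = FALSE)
  }
  resolve_config(cfg)
}

#' Resolve a configuration list into parameter objects
#'
#' @param cfg nested configuration list in the layout of the defaults.
#' @return `lfmm_config` with `$params` holding the validated objects.
#' @export
resolve_config <- function(cfg) {
  problems <- character(0)
  grab <- function(expr) tryCatch(expr, error = function(e) {
    problems <<- c(problems, conditionMessage(e))
    NULL
  })
  params <- list(
    geometry = grab(do.call(geometry_params, cfg$geometry)),
    materials = grab(material_set(
      ecm = do.call(ecm_params, cfg$materials$ecm),
      fiber = do.call(fiber_params, cfg$materials$fiber),
      apon = do.call(apon_params, cfg$materials$apon),
      fiber_stress_mode = cfg$materials$fiber_stress_mode)),
    links = grab(do.call(link_params, cfg$links)),
    solver = grab(do.call(solver_control, cfg$solver)),
    scenario = grab(do.call(scenario_spec, cfg$scenario)))
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(list(raw = cfg, params = params), class = "lfmm_config")
}

#' Execute a configured run
#'
#' Runs the configured scenario and writes its outputs to the output
#' directory: the strain grid and (for connected variants) link-force and
#' balance CSVs, VTK snapshots of the reference and deformed mesh, the
#' resolved configuration echo, and a JSON run manifest with the
#' convergence summary.  Strain percentages in CSV outputs are rounded to
#' 0.1.
#'
#' @param config an `lfmm_config` from [load_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, the solution.
#' @export
run_config <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "lfmm_config"))
  p <- config$params
  set.seed(config$raw$seed)
  dir.create(config$raw$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("running ", p$scenario$model_variant, " model, case ",
      p$scenario$case)
  sol <- run_case(p$scenario, p$geometry, p$links, p$materials, p$solver,
                  steps_disp = config$raw$steps$displacement,
                  steps_act = config$raw$steps$activation)
  od <- config$raw$output_dir
  rep_ <- fiber_strain_report(sol)
  df <- as.data.frame(rep_)
  df$strain_pct <- round(df$strain_pct, 1)
  utils::write.csv(df[, c("face", "section", "interface", "strain_pct")],
                   file.path(od, "strain_grid.csv"), row.names = FALSE)
  lf <- link_forces(sol$mesh, sol$u)
  utils::write.csv(lf, file.path(od, "link_forces.csv"),
                   row.names = FALSE)
  bal <- proximo_distal_balance(sol)
  utils::write.csv(as.data.frame(bal), file.path(od, "balance.csv"),
                   row.names = FALSE)
  write_vtk(sol$mesh, file.path(od, "mesh_reference.vtk"))
  write_vtk(sol$mesh, file.path(od, "mesh_deformed.vtk"), u = sol$u)
  yaml::write_yaml(config$raw, file.path(od, "config_resolved.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("lfmmuscle")),
    r_version = R.version.string,
    config_checksum = sum(utf8ToInt(paste(deparse(config$raw),
                                          collapse = ""))),
    scenario = unclass(p$scenario),
    convergence = list(residual_ratio = sol$residual_ratio,
                       steps = nrow(sol$history),
                       iterations = sum(sol$history$iterations)))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("outputs written to ", od)
  invisible(sol)
}
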