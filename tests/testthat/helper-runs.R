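# Lazily computed, session-cached scenario solutions shared across test
# files (full-size runs take tens of seconds each; each is solved once).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

run_isolated <- function(case)
  cached(paste0("iso_", case),
         run_case(scenario_spec("isolated", case)))

run_extramuscular <- function(case)
  cached(paste0("ext_", case),
         run_case(scenario_spec("extramuscular", case)))

run_epimuscular <- function(case)
  cached(paste0("epi_", case),
         run_case(scenario_spec("epimuscular", case)))

run_sweep <- function(case, factors)
  cached(paste0("sweep_", case, "_", paste(factors, collapse = "_")),
         stiffness_sweep(scenario_spec("extramuscular", case), factors))

strain_of <- function(sol) fiber_strain_report(sol)
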