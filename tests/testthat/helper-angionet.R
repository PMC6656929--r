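# Shared fixtures: the expanded builtin network and the baseline steady state
# are deterministic and expensive enough to compute once per test run.

.cache <- new.env(parent = emptyenv())

ang_net <- function() {
  if (is.null(.cache$net)) .cache$net <- expand_network(builtin_model())
  .cache$net
}

ang_params <- function() default_parameters()
ang_geom <- function() geometry()

ang_baseline_ss <- function() {
  if (is.null(.cache$ss)) {
    sys <- assemble_odes(ang_net(), ang_params(), ang_geom())
    .cache$ss <- run_to_steady_state(sys)
  }
  .cache$ss
}

# parameter set for the toy ligand-receptor model
toy_params <- function(kd = 10e-9, kon = 5e5, r_total_M = 1e-9,
                       geom = geometry()) {
  generate_fixture("ligand_receptor", kd = kd,
                   totals = c(L = 1e-9, R = r_total_M), kon = kon,
                   geom = geom)$params
}

# fluid-equivalent molar observables at a state
fluid_obs <- function(state, weights, geom = ang_geom()) {
  sapply(weights, function(w) sum(w * state[seq_along(w)])) /
    geom$interstitial_fluid_fraction * 1000
}
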