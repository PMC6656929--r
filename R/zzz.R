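# Session cache and high-level convenience wrappers.

the <- new.env(parent = emptyenv())

#' The expanded builtin network (cached per session)
#'
#' Expanding the builtin rule catalogue is deterministic, so the result is
#' computed once per R session and reused.
#'
#' @param refresh Force re-expansion.
#' @return An `angio_network`.
#' @export
angionet_network <- function(refresh = FALSE) {
  if (refresh || is.null(the$network)) {
    the$network <- expand_network(builtin_model())
  }
  the$network
}

#' Baseline steady state of the builtin model
#'
#' Convenience wrapper: expands the builtin network (cached), assembles the
#' ODE system with the shipped calibrated parameters and geometry, and runs
#' it to steady state.
#'
#' @param params,geom Optional overrides of [default_parameters()] /
#'   [geometry()].
#' @return An `angio_ss`.
#' @export
baseline_steady_state <- function(params = default_parameters(),
                                  geom = geometry()) {
  net <- angionet_network()
  sys <- assemble_odes(net, params, geom)
  run_to_steady_state(sys)
}
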