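# broom-style tidiers for the core result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a reaction network
#'
#' @param x An `angio_network`.
#' @param what `"species"` or `"reactions"`.
#' @param ... Unused.
#' @return A tibble ([species_table()] or [reaction_table()]).
#' @export
tidy.angio_network <- function(x, what = c("species", "reactions"), ...) {
  what <- match.arg(what)
  if (what == "species") species_table(x) else reaction_table(x)
}

#' One-row network summary
#' @param x An `angio_network`.
#' @param ... Unused.
#' @return One-row tibble of counts.
#' @export
glance.angio_network <- function(x, ...) network_summary(x)$counts

#' Tidy a steady state into a concentration table
#'
#' @param x An `angio_ss`.
#' @param units Fluid-phase units (`"pM"`, `"nM"`, `"M"`).
#' @param ... Unused.
#' @return Tibble with `id`, `compartment`, `conc` and a `units` column
#'   (fluid-phase interstitial concentrations).
#' @export
tidy.angio_ss <- function(x, units = "pM", ...) {
  geom <- x$sys$geom
  tibble(id = x$sys$net$ids,
         compartment = x$sys$net$compartment,
         conc = tissue_to_fluid_concentration(unname(x$state), geom, units),
         units = paste0(units, " (fluid)"))
}

#' One-row steady-state summary
#' @param x An `angio_ss`.
#' @param ... Unused.
#' @return One-row tibble: convergence time, flag, state dimension.
#' @export
glance.angio_ss <- function(x, ...) {
  tibble(time_s = x$time, converged = x$converged, n_species = x$sys$n)
}

#' Tidy a trajectory into long form
#'
#' @param x An `angio_traj`.
#' @param units Fluid-phase units.
#' @param ... Unused.
#' @return Tibble with `time_s`, `id`, `conc`, `units`.
#' @export
tidy.angio_traj <- function(x, units = "pM", ...) {
  geom <- x$sys$geom
  n <- x$sys$n
  st <- x$state[, seq_len(n), drop = FALSE]
  as_tibble(st) %>%
    mutate(time_s = x$times) %>%
    tidyr::pivot_longer(-time_s, names_to = "id", values_to = "conc") %>%
    mutate(conc = tissue_to_fluid_concentration(conc, geom, units),
           units = paste0(units, " (fluid)"))
}

#' Tidy a pulse result
#' @param x An `angio_pulse`.
#' @param ... Unused.
#' @return The tidy trajectory tibble (time, observable, conc in pM fluid).
#' @export
tidy.angio_pulse <- function(x, ...) x$trajectory

#' One-row pulse summary
#' @param x An `angio_pulse`.
#' @param ... Unused.
#' @return One-row tibble: cHSPG level and peak free PF4.
#' @export
glance.angio_pulse <- function(x, ...) {
  tibble(chspg_level = x$chspg_level, peak_pf4_nM = x$peak_pf4_nM)
}
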