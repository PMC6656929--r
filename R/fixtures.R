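# Test-fixture generator: small toy binding networks with closed-form or
# numerically root-found oracles stored alongside them.

fixture_templates <- function() c("ligand_receptor", "competition", "depot_decay")

#' Generate a self-contained toy fixture with its analytic oracle
#'
#' Templates:
#' * `ligand_receptor`: L + R <-> C; the oracle equilibrium comes from the
#'   quadratic closed form.
#' * `competition`: one ligand, two receptors (L + R1 <-> C1, L + R2 <-> C2);
#'   the oracle solves the two-conservation-law system numerically.
#' * `depot_decay`: a depot releasing into a non-degrading pool; the oracle
#'   is the released fraction `1 - exp(-k t)`.
#'
#' @param template One of [fixture_templates()].
#' @param kd Dissociation constant(s), M (binding templates).
#' @param totals Total ligand / receptor concentrations, M fluid-equivalent.
#' @param kon Association rate (1/(M s)).
#' @param k_rel Release constant (depot template, 1/s).
#' @param geom An `angio_geometry`.
#' @return List with `spec` (an `angio_model`), `params` (`angio_params`),
#'   `oracle` (template-specific reference values) and `template`.
#' @export
generate_fixture <- function(template = "ligand_receptor",
                             kd = 10e-9, totals = c(L = 1e-9, R = 1e-9),
                             kon = 5e5, k_rel = 2.8e-5,
                             geom = geometry()) {
  if (!template %in% fixture_templates()) {
    abort(paste0("unknown fixture template '", template, "'"))
  }
  mk_params <- function(binding, densities, uni = c()) {
    structure(list(binding = binding, unimolecular = uni, catalytic = c(),
                   half_life = c(), production = c(), densities = densities),
              class = "angio_params")
  }
  to_cells <- function(molar) {
    # express a fluid-equivalent molar total as receptors/cell at the
    # endothelial density
    fluid_to_tissue_concentration(molar, geom) * AVOGADRO / geom$cells_ec_per_cm3
  }

  if (template == "ligand_receptor") {
    spec <- toy_model()
    params <- mk_params(
      binding = list(lr = list(kon = kon, koff = kon * kd)),
      densities = tibble(species = "R", side = "ec", value = to_cells(totals[["R"]]),
                         units = "receptors/cell", provenance = "fixture"))
    L0 <- totals[["L"]]; R0 <- totals[["R"]]
    b <- -(L0 + R0 + kd)
    Ceq <- (-b - sqrt(b^2 - 4 * L0 * R0)) / 2
    oracle <- list(n_species = 3L, n_reactions = 2L,
                   equilibrium_M = c(C = Ceq, L = L0 - Ceq, R = R0 - Ceq))
  } else if (template == "competition") {
    stopifnot(length(kd) == 2L, all(c("L", "R1", "R2") %in% names(totals)))
    M <- list(monomer("L", "b", "soluble"),
              monomer("R1", "b", "surface_fixed"),
              monomer("R2", "b", "surface_fixed"))
    names(M) <- c("L", "R1", "R2")
    seeds <- list(
      c(free_species("L", "interstitium", M), list(init = "zero")),
      c(free_species("R1", "endothelial_surface", M), list(init = "density:R1:ec")),
      c(free_species("R2", "endothelial_surface", M), list(init = "density:R2:ec")))
    rules <- list(
      bind_rule("L.R1", P1("L", comp = "interstitium"), "b",
                P1("R1", comp = "surface"), "b", "kon_lr1", "koff_lr1"),
      bind_rule("L.R2", P1("L", comp = "interstitium"), "b",
                P1("R2", comp = "surface"), "b", "kon_lr2", "koff_lr2"))
    spec <- model_spec(M, seeds, rules, name = "toy_competition")
    params <- mk_params(
      binding = list(lr1 = list(kon = kon, koff = kon * kd[[1L]]),
                     lr2 = list(kon = kon, koff = kon * kd[[2L]])),
      densities = tibble(species = c("R1", "R2"), side = "ec",
                         value = c(to_cells(totals[["R1"]]), to_cells(totals[["R2"]])),
                         units = "receptors/cell", provenance = "fixture"))
    # oracle: free ligand solves L + sum_i Ri_tot L/(L+Kd_i) = L_tot
    L0 <- totals[["L"]]
    fr <- function(L) {
      L + totals[["R1"]] * L / (L + kd[[1L]]) + totals[["R2"]] * L / (L + kd[[2L]]) - L0
    }
    Lf <- stats::uniroot(fr, c(0, L0), tol = 1e-18)$root
    oracle <- list(
      n_species = 5L, n_reactions = 4L,
      equilibrium_M = c(L = Lf,
                        C1 = totals[["R1"]] * Lf / (Lf + kd[[1L]]),
                        C2 = totals[["R2"]] * Lf / (Lf + kd[[2L]])))
  } else {
    M <- list(monomer("D", character(), "soluble"))
    names(M) <- "D"
    seeds <- list(c(free_species("D", "interstitium", M), list(init = "zero")))
    spec <- model_spec(M, seeds, list(), name = "toy_depot")
    params <- mk_params(binding = list(),
                        densities = tibble(species = character(), side = character(),
                                           value = numeric(), units = character(),
                                           provenance = character()))
    oracle <- list(released_fraction = function(t) 1 - exp(-k_rel * t),
                   k_rel = k_rel)
  }
  list(template = template, spec = spec, params = params, oracle = oracle)
}
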