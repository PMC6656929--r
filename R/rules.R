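# Reaction rules and the model specification container.

rule_classes <- function() {
  c("binding", "unbinding", "coupling", "production", "degradation",
    "internalization", "catalytic_conversion")
}

#' Declare a reaction rule
#'
#' Rule classes and their payloads:
#' * `binding` / `coupling`: two reactant patterns joined by a new bond
#'   (`bond = list(c(instance, site), c(instance, site))`, the first relative
#'   to pattern 1, the second to pattern 2). `coupling` is binding between two
#'   surface-anchored partners; kinetically it is treated identically.
#' * `unbinding`: one reactant pattern; `delbond` names the index of the
#'   pattern bond to delete (the complex splits if it disconnects).
#' * `production`: no reactants; `products` holds the produced seed complex.
#' * `degradation`: one pattern that must cover a whole species; removes it.
#' * `internalization`: one pattern; the matched species is removed, its
#'   surface-fixed monomers are returned unbonded to the surface pool and the
#'   soluble cargo is destroyed (receptor recycling with constant totals).
#' * `catalytic_conversion`: two whole-species patterns (enzyme, substrate);
#'   `products` lists the two product complexes explicitly (e.g. proMMP9 ->
#'   MMP9 activation, TSP1 -> TSP1c and V165 -> V114 cleavage).
#'
#' @param id Unique rule identifier.
#' @param class One of the rule classes above.
#' @param reactants List of [pattern()]s (0, 1 or 2 of them).
#' @param rate_fwd Name of the forward rate constant in the parameter set.
#' @param rate_rev Optional name of the reverse rate constant (reversible
#'   binding); `NA` for irreversible rules.
#' @param bond,delbond,products,conversion Class-specific payloads.
#' @param notes Free-text provenance note (catalogue mapping).
#' @return An object of class `angio_rule`.
#' @export
rule <- function(id, class, reactants, rate_fwd, rate_rev = NA_character_,
                 bond = NULL, delbond = NULL, products = NULL,
                 conversion = NULL, notes = "") {
  if (!class %in% rule_classes()) abort(paste0("unknown rule_class '", class, "'"))
  structure(list(id = id, class = class, reactants = reactants,
                 rate_fwd = rate_fwd, rate_rev = rate_rev, bond = bond,
                 delbond = delbond, products = products,
                 conversion = conversion, notes = notes),
            class = "angio_rule")
}

is_reversible <- function(r) !is.na(r$rate_rev)

#' Assemble a model specification
#'
#' @param monomers Named list of [monomer()] declarations.
#' @param seeds List of seed species: each a list with `complex`
#'   (an `angio_complex`) and `init` (name of the initial-amount entry in the
#'   parameter set, or `"zero"`).
#' @param rules List of [rule()]s.
#' @param name Model name.
#' @return An object of class `angio_model`.
#' @export
model_spec <- function(monomers, seeds, rules, name = "model") {
  names(monomers) <- vapply(monomers, function(m) m$name, character(1))
  ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(ids)) abort("duplicate rule ids")
  names(rules) <- ids
  structure(list(name = name, monomers = monomers, seeds = seeds,
                 rules = rules),
            class = "angio_model")
}

#' @export
print.angio_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<angio_model> %s: %d monomer types, %d seed species, %d rules\n",
              x$name, s$n_monomers, s$n_seeds, s$n_rules))
  invisible(x)
}

#' Summarise a model specification
#'
#' @param spec An `angio_model`.
#' @return A one-row tibble with monomer, seed-species and rule counts and the
#'   number of rate names referenced.
#' @export
model_summary <- function(spec) {
  tibble(
    model = spec$name,
    n_monomers = length(spec$monomers),
    n_seeds = length(spec$seeds),
    n_rules = length(spec$rules),
    n_rate_names = length(rate_names(spec))
  )
}

rate_names <- function(spec) {
  nm <- unlist(lapply(spec$rules, function(r) c(r$rate_fwd, r$rate_rev)))
  sort(unique(nm[!is.na(nm)]))
}

# ---- structural validation --------------------------------------------------

pattern_monomer_errors <- function(pat, monomers, where) {
  errs <- character(0)
  for (k in seq_along(pat$types)) {
    t <- pat$types[[k]]
    if (is.null(monomers[[t]])) {
      errs <- c(errs, paste0(where, ": undeclared monomer '", t, "'"))
      next
    }
    for (s in names(pat$cond[[k]])) {
      if (!s %in% monomers[[t]]$sites) {
        errs <- c(errs, paste0(where, ": monomer '", t, "' has no site '", s, "'"))
      }
    }
  }
  for (b in pat$pbonds) {
    for (end in list(c(b$i, b$si), c(b$j, b$sj))) {
      t <- pat$types[[as.integer(end[[1]])]]
      if (!is.null(monomers[[t]]) && !end[[2]] %in% monomers[[t]]$sites) {
        errs <- c(errs, paste0(where, ": monomer '", t, "' has no site '", end[[2]], "'"))
      }
    }
  }
  errs
}

#' Validate structural consistency of a model specification
#'
#' Checks, per invariant: monomers referenced by rules and seeds are declared
#' with the right sites; at most two reactant patterns per rule; production
#' rules have empty reactant lists; monomer counts are conserved by binding,
#' unbinding and conversion rules (conversion via an explicit type map); no
#' rule couples monomers across the two cell surfaces (guaranteed by
#' compartment-aware expansion, checked here for explicit compartment tags);
#' soluble monomers carry no bonds to two different surfaces in seeds.
#'
#' @param spec An `angio_model`.
#' @return A tibble with columns `check`, `ok`, `detail`; attribute
#'   `valid` is `TRUE` when all checks pass.
#' @export
validate_spec <- function(spec) {
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, ok = ok, detail = detail)
  }

  errs <- character(0)
  for (r in spec$rules) {
    for (pat in r$reactants) {
      errs <- c(errs, pattern_monomer_errors(pat, spec$monomers, paste0("rule ", r$id)))
    }
    for (pr in r$products %||% list()) {
      for (k in seq_along(pr$types)) {
        if (is.null(spec$monomers[[pr$types[[k]]]])) {
          errs <- c(errs, paste0("rule ", r$id, ": undeclared monomer '", pr$types[[k]], "'"))
        }
      }
    }
  }
  add("monomers_and_sites_declared", length(errs) == 0L,
      paste(errs, collapse = "; "))

  bad <- vapply(spec$rules, function(r) length(r$reactants) > 2L, logical(1))
  add("max_two_reactant_patterns", !any(bad),
      paste(names(spec$rules)[bad], collapse = ", "))

  bad <- vapply(spec$rules, function(r) {
    r$class == "production" && length(r$reactants) != 0L
  }, logical(1))
  add("production_rules_have_no_reactants", !any(bad),
      paste(names(spec$rules)[bad], collapse = ", "))

  bad <- vapply(spec$rules, function(r) {
    if (r$class != "catalytic_conversion") return(FALSE)
    length(r$reactants) != 2L || length(r$products) != 2L
  }, logical(1))
  add("conversion_rules_are_binary", !any(bad),
      paste(names(spec$rules)[bad], collapse = ", "))

  # monomer-count conservation for conversion rules, via the conversion map
  bad <- character(0)
  for (r in spec$rules) {
    if (r$class != "catalytic_conversion") next
    n_in <- sum(vapply(r$reactants, pat_size, integer(1)))
    n_out <- sum(vapply(r$products, cpx_size, integer(1)))
    if (n_in != n_out) bad <- c(bad, r$id)
  }
  add("conversion_conserves_monomer_count", length(bad) == 0L,
      paste(bad, collapse = ", "))

  bad <- character(0)
  for (sd in spec$seeds) {
    if (!cpx_connected(sd$complex)) bad <- c(bad, canonical_form(sd$complex))
  }
  add("seed_species_connected", length(bad) == 0L, paste(bad, collapse = "; "))

  # soluble monomers must not be declared with surface mobility sites --
  # approximated structurally: seeds in the interstitium contain no
  # surface-fixed monomers
  bad <- character(0)
  for (sd in spec$seeds) {
    mob <- vapply(sd$complex$types, function(t) spec$monomers[[t]]$mobility, character(1))
    if (sd$complex$compartment == "interstitium" && any(mob == "surface_fixed")) {
      bad <- c(bad, canonical_form(sd$complex))
    }
    if (sd$complex$compartment %in% surface_tags() && !any(mob == "surface_fixed")) {
      bad <- c(bad, canonical_form(sd$complex))
    }
  }
  add("seed_compartments_consistent", length(bad) == 0L, paste(bad, collapse = "; "))

  out <- bind_rows(checks)
  attr(out, "valid") <- all(out$ok)
  out
}

#' Error out when a model specification is invalid
#' @param spec An `angio_model`.
#' @return `spec`, invisibly, when valid.
#' @export
assert_valid_spec <- function(spec) {
  rep <- validate_spec(spec)
  if (!attr(rep, "valid")) {
    bad <- rep[!rep$ok, ]
    abort(paste0("invalid model spec: ",
                 paste(paste0(bad$check, " (", bad$detail, ")"), collapse = "; ")))
  }
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
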