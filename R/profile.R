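# Distribution profiles and the angiogenic ratio: categorize every
# factor-containing species and aggregate steady-state concentrations.

factor_families <- function() {
  list(VEGF = c("V165", "V121", "V114"),
       FGF2 = "FGF2",
       TSP1 = c("TSP1", "TSP1c"),
       PF4 = "PF4")
}

pro_receptors <- function() c("VEGFR1", "VEGFR2", "NRP1")
tsp1_receptors <- function() c("CD36", "CD47", "LRP1", "B1")
pf4_receptors <- function() c("CXCR3", "LRP1")

# is instance i's site bound to one of the given partner types?
inst_bound_to <- function(cpx, i, site, partner_types) {
  p <- cpx$nbr[[i]][[site]]
  !is.null(p) && cpx$types[[p$j]] %in% partner_types
}

# per-species, per-factor category assignment (see the methods vignette):
# surface species split into signaling vs non-signaling forms; interstitial
# species into unbound / iHSPG-bound / factor-bound / cleaved-inactive.
categorize_species <- function(net) {
  fams <- factor_families()
  rows <- list()
  for (s in seq_along(net$species)) {
    cpx <- net$species[[s]]
    types <- cpx$types
    on_surface <- cpx$compartment %in% surface_tags()
    has_ihspg <- "iHSPG" %in% types
    n_fgfr1 <- sum(types == "FGFR1")
    tsp1_ligated <- any(vapply(seq_along(types), function(i) {
      types[[i]] == "TSP1" && inst_bound_to(cpx, i, "r", tsp1_receptors())
    }, logical(1)))
    for (fam in names(fams)) {
      members <- which(types %in% fams[[fam]])
      if (!length(members)) next
      w <- length(members)
      cat_ <- if (on_surface) {
        sig <- switch(fam,
          VEGF = !tsp1_ligated && any(vapply(members, function(i) {
            (types[[i]] %in% c("V165", "V121") &&
               inst_bound_to(cpx, i, "r", c("VEGFR1", "VEGFR2"))) ||
              (types[[i]] == "V165" && inst_bound_to(cpx, i, "n", "NRP1"))
          }, logical(1))),
          FGF2 = n_fgfr1 >= 2L,
          TSP1 = tsp1_ligated,
          PF4 = any(vapply(members, function(i) {
            inst_bound_to(cpx, i, "r", pf4_receptors())
          }, logical(1))))
        if (sig) "surface:signaling" else "surface:non_signaling"
      } else {
        cleaved <- all(types[members] %in% c("V114", "TSP1c"))
        n_fams <- sum(vapply(fams, function(tt) any(types %in% tt), logical(1)))
        if (cleaved) "interstitial:cleaved_inactive"
        else if (has_ihspg) "interstitial:ihspg_bound"
        else if (n_fams >= 2L) "interstitial:factor_bound"
        else if (cpx_size(cpx) == 1L) "interstitial:unbound"
        else "interstitial:factor_bound"
      }
      rows[[length(rows) + 1L]] <- tibble(
        index = s, id = net$ids[[s]], factor = fam, weight = w, category = cat_)
    }
  }
  bind_rows(rows)
}

profile_categories <- function() {
  c("surface:signaling", "surface:non_signaling", "interstitial:unbound",
    "interstitial:ihspg_bound", "interstitial:factor_bound",
    "interstitial:cleaved_inactive")
}

#' Distribution profile of the angiogenic factors
#'
#' For each factor (VEGF, FGF2, TSP1, PF4), the percentage of its total
#' tissue amount found in each form: cell-surface signaling complexes,
#' cell-surface non-signaling forms (cHSPG-bound and non-signaling receptor
#' forms), interstitial unbound, iHSPG-bound, bound to another angiogenic
#' factor, and cleaved/inactive. Complexes containing two tracked factors
#' count toward both factors' factor-bound categories; percentages are
#' instance-weighted so each factor's column sums to 100.
#'
#' @param ss An `angio_ss` (or named state vector with `net` supplied).
#' @param net The expanded `angio_network`.
#' @return A tibble of class `angio_profile` with columns `factor`,
#'   `category`, `percent`; the species-to-category membership table is
#'   attached as attribute `membership`.
#' @export
distribution_profile <- function(ss, net = ss$sys$net) {
  state <- if (inherits(ss, "angio_ss")) ss$state else ss
  mem <- categorize_species(net)
  mem$conc <- state[mem$index] * mem$weight
  prof <- mem %>%
    group_by(factor, category) %>%
    summarise(amount = sum(conc), .groups = "drop_last") %>%
    mutate(total = sum(amount),
           percent = ifelse(total > 0, 100 * amount / total, 0)) %>%
    ungroup() %>%
    select(factor, category, percent)
  full <- tidyr::expand_grid(factor = names(factor_families()),
                             category = profile_categories())
  prof <- full %>%
    left_join(prof, by = c("factor", "category")) %>%
    mutate(percent = tidyr::replace_na(percent, 0))
  bad <- prof %>% group_by(factor) %>% summarise(s = sum(percent)) %>%
    filter(s > 0, abs(s - 100) > 0.01)   # absent factors report all-zero rows
  if (nrow(bad)) abort("profile closure violated: factor percentages do not sum to 100")
  structure(as_tibble(prof), membership = mem, class = c("angio_profile", class(prof)))
}

# index sets of signaling complexes per pathway, with an `anti` flag
signaling_membership <- function(net) {
  mem <- categorize_species(net)
  sig <- mem[mem$category == "surface:signaling", ]
  split(sig$index, sig$factor)
}

#' Angiogenic ratio of a steady state
#'
#' The ratio of the summed concentrations of pro-angiogenic signaling
#' complexes (VEGF isoforms bound to VEGFR1, VEGFR2 or NRP1; dimerized FGF2
#' signaling complexes) to anti-angiogenic signaling complexes (TSP1 bound to
#' CD36, CD47, LRP1 or beta-1 integrins; PF4 bound to CXCR3 or LRP1). Values
#' above 1 indicate a tissue state favoring pro-angiogenic signaling.
#'
#' @param ss An `angio_ss`, or a named state vector (mol/cm^3 tissue).
#' @param net The `angio_network`.
#' @return A one-row tibble of class `angio_ratio`: `numerator`,
#'   `denominator` (mol/cm^3 tissue), `ratio`, `finite`; per-complex
#'   components in attribute `components`.
#' @export
angiogenic_ratio <- function(ss, net = ss$sys$net) {
  state <- if (inherits(ss, "angio_ss")) ss$state else ss
  sig <- signaling_membership(net)
  tot <- function(fams) {
    idx <- unique(unlist(sig[fams]))
    if (!length(idx)) 0 else sum(state[idx])
  }
  num <- tot(c("VEGF", "FGF2"))
  den <- tot(c("TSP1", "PF4"))
  comp <- bind_rows(lapply(names(sig), function(f) {
    tibble(pathway = f, index = sig[[f]], id = net$ids[sig[[f]]],
           conc = unname(state[sig[[f]]]),
           side = if (f %in% c("VEGF", "FGF2")) "pro" else "anti")
  }))
  out <- tibble(numerator = num, denominator = den,
                ratio = if (den > 0) num / den else Inf,
                finite = den > 0)
  structure(out, components = comp, class = c("angio_ratio", class(out)))
}

# ---- tracked observables ----------------------------------------------------

# instance-weighted index/weight pairs for a predicate over (cpx, instance)
species_weight <- function(net, pred) {
  w <- numeric(length(net$ids))
  for (s in seq_along(net$species)) {
    cpx <- net$species[[s]]
    for (i in seq_along(cpx$types)) if (pred(cpx, i)) w[[s]] <- w[[s]] + 1
  }
  w
}

#' Weight vectors for the standard tracked observables
#'
#' Returns a named list of per-species weight vectors w such that
#' `sum(w * state)` is the observable in mol/cm^3 tissue: unbound and total
#' factor pools, per-receptor bound VEGF, FGF2 complex classes, and the
#' pathway signaling totals used in scans.
#'
#' @param net An `angio_network`.
#' @return Named list of numeric vectors.
#' @export
observable_weights <- function(net) {
  ids <- net$ids
  single <- function(id) {
    w <- numeric(length(ids)); w[match(id, ids)] <- 1; w
  }
  bound_to <- function(ltypes, site, rtypes) {
    species_weight(net, function(cpx, i) {
      cpx$types[[i]] %in% ltypes && inst_bound_to(cpx, i, site, rtypes)
    })
  }
  fam_total <- function(types) {
    species_weight(net, function(cpx, i) cpx$types[[i]] %in% types)
  }
  sig <- signaling_membership(net)
  sig_w <- lapply(sig, function(idx) {
    w <- numeric(length(ids)); w[idx] <- 1; w
  })
  # FGF2 complex classes
  fgf2_fgfr1_monomer <- species_weight(net, function(cpx, i) {
    cpx$types[[i]] == "FGF2" && inst_bound_to(cpx, i, "r", "FGFR1") &&
      is.null(cpx$nbr[[i]][["h"]]) && sum(cpx$types == "FGFR1") == 1L
  })
  trimer <- species_weight(net, function(cpx, i) {
    cpx$types[[i]] == "FGF2" && inst_bound_to(cpx, i, "r", "FGFR1") &&
      inst_bound_to(cpx, i, "h", "cHSPG") && sum(cpx$types == "FGFR1") == 1L
  })
  dimer <- numeric(length(ids))
  for (s in seq_along(net$species)) {
    if (sum(net$species[[s]]$types == "FGFR1") >= 2L) dimer[[s]] <- 1
  }
  list(
    VEGF_unbound = single("V165@interstitium") + single("V121@interstitium"),
    V165_unbound = single("V165@interstitium"),
    V121_unbound = single("V121@interstitium"),
    FGF2_unbound = single("FGF2@interstitium"),
    TSP1_unbound = single("TSP1@interstitium"),
    PF4_unbound = single("PF4@interstitium"),
    VEGF_total = fam_total(c("V165", "V121", "V114")),
    FGF2_total = fam_total("FGF2"),
    TSP1_total = fam_total(c("TSP1", "TSP1c")),
    PF4_total = fam_total("PF4"),
    MMP3_total = fam_total("MMP3"),
    MMP9_total = fam_total(c("proMMP9", "MMP9")),
    VEGF_R1 = bound_to(c("V165", "V121"), "r", "VEGFR1"),
    VEGF_R2 = bound_to(c("V165", "V121"), "r", "VEGFR2"),
    VEGF_NRP1 = bound_to("V165", "n", "NRP1"),
    FGF2_FGFR1_monomer = fgf2_fgfr1_monomer,
    FGF2_trimer = trimer,
    FGF2_dimer = dimer,
    VEGF_signaling = sig_w$VEGF %||% numeric(length(ids)),
    FGF2_signaling = sig_w$FGF2 %||% numeric(length(ids)),
    TSP1_signaling = sig_w$TSP1 %||% numeric(length(ids)),
    PF4_signaling = sig_w$PF4 %||% numeric(length(ids))
  )
}

# evaluate observables for a state (or trajectory matrix) -> named numeric
# (or matrix rows = times)
eval_observables <- function(state, weights) {
  if (is.matrix(state)) {
    ns <- length(weights[[1L]])
    sapply(weights, function(w) as.numeric(state[, seq_len(ns), drop = FALSE] %*% w))
  } else {
    vapply(weights, function(w) sum(w * state[seq_along(w)]), numeric(1))
  }
}
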