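# Rule expansion: apply the rule catalogue to the seed species until no new
# species appear, producing the concrete reaction network (the generator step
# rule-based frameworks perform before ODE export).

join_complexes <- function(A, B, bond_a, bond_b, comp) {
  nA <- cpx_size(A)
  types <- c(A$types, B$types)
  nbr <- c(A$nbr, lapply(B$nbr, function(x) {
    lapply(x, function(p) if (is.null(p)) NULL else list(j = p$j + nA, site = p$site))
  }))
  i <- bond_a[[1L]]; si <- bond_a[[2L]]
  j <- bond_b[[1L]] + nA; sj <- bond_b[[2L]]
  nbr[[i]][[si]] <- list(j = j, site = sj)
  nbr[[j]][[sj]] <- list(j = i, site = si)
  structure(list(types = types, nbr = nbr, compartment = comp),
            class = "angio_complex")
}

bond_within <- function(A, i, si, j, sj) {
  nbr <- A$nbr
  nbr[[i]][[si]] <- list(j = j, site = sj)
  nbr[[j]][[sj]] <- list(j = i, site = si)
  structure(list(types = A$types, nbr = nbr, compartment = A$compartment),
            class = "angio_complex")
}

delete_bond <- function(A, i, si) {
  p <- A$nbr[[i]][[si]]
  nbr <- A$nbr
  nbr[[i]][si] <- list(NULL)
  nbr[[p$j]][p$site] <- list(NULL)
  structure(list(types = A$types, nbr = nbr, compartment = A$compartment),
            class = "angio_complex")
}

pair_compartment <- function(tagA, tagB) {
  sa <- tagA %in% surface_tags(); sb <- tagB %in% surface_tags()
  if (sa && sb) {
    if (!identical(tagA, tagB)) return(NULL)  # cross-surface binding is illegal
    return(tagA)
  }
  if (sa) return(tagA)
  if (sb) return(tagB)
  "interstitium"
}

#' Expand a model specification into a concrete reaction network
#'
#' Applies every rule to the growing species set until a fixpoint is reached:
#' re-applying all rules adds no species and no reactions. Species are ordered
#' by canonical id, so the result is invariant under permutations of seeds and
#' rules. Reversible binding rules emit both directed reactions.
#'
#' @param spec An `angio_model` (validated).
#' @param max_species Abort with an "unbounded polymerization" error if the
#'   species count exceeds this (default 1000).
#' @return An object of class `angio_network` with fields `ids`, `species`,
#'   `compartment`, `init` and a `reactions` tibble (columns `rule`,
#'   `reactant1`, `reactant2`, `products` (list), `rate`, `mult`).
#' @export
expand_network <- function(spec, max_species = 1000L) {
  assert_valid_spec(spec)
  M <- spec$monomers

  sp <- list()            # complexes
  ids <- character(0)
  init <- character(0)
  idx_of <- new.env(parent = emptyenv())

  add_species <- function(cpx, init_spec = "zero") {
    key <- canonical_form(cpx)
    got <- idx_of[[key]]
    if (!is.null(got)) return(got)
    k <- length(sp) + 1L
    if (k > max_species) {
      abort(paste0("species count exceeded max_species = ", max_species,
                   ": possible unbounded polymerization"))
    }
    sp[[k]] <<- cpx; ids[[k]] <<- key; init[[k]] <<- init_spec
    idx_of[[key]] <<- k
    k
  }

  for (sd in spec$seeds) add_species(sd$complex, sd$init %||% "zero")

  reactions <- list()
  rxn_seen <- new.env(parent = emptyenv())
  add_reaction <- function(rule_id, reactants, products, rate, mult) {
    key <- paste(rule_id, paste(reactants, collapse = "+"), ">",
                 paste(sort(products), collapse = "+"), rate)
    got <- rxn_seen[[key]]
    if (!is.null(got)) {
      reactions[[got]]$mult <<- reactions[[got]]$mult + mult
      return(invisible(NULL))
    }
    k <- length(reactions) + 1L
    reactions[[k]] <<- list(rule = rule_id, reactants = reactants,
                            products = products, rate = rate, mult = mult)
    rxn_seen[[key]] <- k
    invisible(NULL)
  }

  # cached pattern matches: match_cache[[rule_id]][[pattern index]] is a list
  # species index (character) -> list of embeddings
  rules <- spec$rules
  match_cache <- lapply(rules, function(r) {
    lapply(seq_along(r$reactants), function(i) list())
  })

  register_matches <- function(si) {
    cpx <- sp[[si]]
    for (rn in names(rules)) {
      r <- rules[[rn]]
      for (pi in seq_along(r$reactants)) {
        pat <- r$reactants[[pi]]
        m <- if (r$class %in% c("degradation", "catalytic_conversion")) {
          match_whole(pat, cpx)
        } else {
          match_pattern(pat, cpx)
        }
        if (length(m)) match_cache[[rn]][[pi]][[as.character(si)]] <<- m
      }
    }
  }

  products_of_split <- function(cpx) {
    comps <- cpx_components(cpx)
    vapply(comps, function(idx) {
      add_species(cpx_induce(cpx, idx, M))
    }, integer(1))
  }

  apply_binding <- function(r, ia, ib, ma, mb) {
    A <- sp[[ia]]; B <- sp[[ib]]
    comp <- pair_compartment(A$compartment, B$compartment)
    if (is.null(comp)) return(invisible(NULL))
    for (m1 in ma) {
      i <- m1[[as.integer(r$bond[[1L]][[1L]])]]; si <- r$bond[[1L]][[2L]]
      for (m2 in mb) {
        j <- m2[[as.integer(r$bond[[2L]][[1L]])]]; sj <- r$bond[[2L]][[2L]]
        Cx <- join_complexes(A, B, list(i, si), list(j, sj), comp)
        ic <- add_species(Cx)
        add_reaction(r$id, c(ia, ib), ic, r$rate_fwd, 1)
        if (is_reversible(r)) add_reaction(r$id, ic, c(ia, ib), r$rate_rev, 1)
      }
    }
  }

  apply_unbinding <- function(r, ia, ma) {
    A <- sp[[ia]]
    b <- r$reactants[[1L]]$pbonds[[r$delbond]]
    for (m in ma) {
      Cx <- delete_bond(A, m[[b$i]], b$si)
      prods <- products_of_split(Cx)
      add_reaction(r$id, ia, prods, r$rate_fwd, 1)
    }
  }

  apply_internalization <- function(r, ia, ma) {
    A <- sp[[ia]]
    keep <- which(vapply(A$types, function(t) M[[t]]$mobility == "surface_fixed",
                         logical(1)))
    prods <- vapply(keep, function(i) {
      add_species(complex_new(A$types[[i]], list(), A$compartment, M))
    }, integer(1))
    add_reaction(r$id, ia, prods, r$rate_fwd, length(ma))
  }

  apply_catalytic <- function(r, ia, ib) {
    prods <- vapply(r$products, add_species, integer(1))
    add_reaction(r$id, c(ia, ib), prods, r$rate_fwd, 1)
  }

  # productions are state-independent; emit once
  for (r in rules) {
    if (r$class == "production") {
      prods <- vapply(r$products, add_species, integer(1))
      add_reaction(r$id, integer(0), prods, r$rate_fwd, 1)
    }
  }

  done_pairs <- new.env(parent = emptyenv())
  frontier <- seq_along(sp)
  for (si in frontier) register_matches(si)

  while (length(frontier)) {
    n_before <- length(sp)
    for (rn in names(rules)) {
      r <- rules[[rn]]
      if (r$class %in% c("binding", "coupling", "catalytic_conversion")) {
        c1 <- match_cache[[rn]][[1L]]; c2 <- match_cache[[rn]][[2L]]
        for (a in names(c1)) {
          for (b in names(c2)) {
            ia <- as.integer(a); ib <- as.integer(b)
            if (!(ia %in% frontier || ib %in% frontier)) next
            key <- paste(rn, a, b)
            if (!is.null(done_pairs[[key]])) next
            done_pairs[[key]] <- TRUE
            if (r$class == "catalytic_conversion") {
              apply_catalytic(r, ia, ib)
            } else {
              apply_binding(r, ia, ib, c1[[a]], c2[[b]])
            }
          }
        }
      } else if (r$class %in% c("unbinding", "degradation", "internalization")) {
        c1 <- match_cache[[rn]][[1L]]
        for (a in names(c1)) {
          ia <- as.integer(a)
          if (!(ia %in% frontier)) next
          key <- paste(rn, a)
          if (!is.null(done_pairs[[key]])) next
          done_pairs[[key]] <- TRUE
          if (r$class == "unbinding") {
            apply_unbinding(r, ia, c1[[a]])
          } else if (r$class == "degradation") {
            add_reaction(r$id, ia, integer(0), r$rate_fwd, length(c1[[a]]))
          } else {
            apply_internalization(r, ia, c1[[a]])
          }
        }
      }
    }
    n_after <- length(sp)
    frontier <- if (n_after > n_before) seq.int(n_before + 1L, n_after) else integer(0)
    for (si in frontier) register_matches(si)
  }

  # canonical ordering: sort by id, remap all reactions
  ord <- order(ids)
  remap <- integer(length(ids)); remap[ord] <- seq_along(ids)
  rx <- tibble(
    rule = vapply(reactions, function(x) x$rule, character(1)),
    reactant1 = vapply(reactions, function(x) {
      if (length(x$reactants) >= 1L) remap[x$reactants[[1L]]] else NA_integer_
    }, integer(1)),
    reactant2 = vapply(reactions, function(x) {
      if (length(x$reactants) >= 2L) remap[x$reactants[[2L]]] else NA_integer_
    }, integer(1)),
    products = lapply(reactions, function(x) sort(remap[x$products])),
    rate = vapply(reactions, function(x) x$rate, character(1)),
    mult = vapply(reactions, function(x) x$mult, numeric(1))
  )
  rx <- rx[order(rx$rule, rx$reactant1, rx$reactant2,
                 vapply(rx$products, function(p) paste(p, collapse = ","), character(1)),
                 rx$rate), ]

  structure(list(
    ids = ids[ord],
    species = sp[ord],
    compartment = vapply(sp[ord], function(x) x$compartment, character(1)),
    init = init[ord],
    reactions = rx,
    spec = spec
  ), class = "angio_network")
}

#' @export
print.angio_network <- function(x, ...) {
  cat(sprintf("<angio_network> %d species, %d reactions\n",
              length(x$ids), nrow(x$reactions)))
  invisible(x)
}

#' Summarise a reaction network
#'
#' @param net An `angio_network`.
#' @return A list with `counts` (one-row tibble: species, reactions,
#'   per-compartment species) and `per_rule` (reactions per rule).
#' @export
network_summary <- function(net) {
  comp <- table(factor(net$compartment, levels = compartments()))
  counts <- tibble(
    n_species = length(net$ids),
    n_reactions = nrow(net$reactions),
    n_endothelial_surface = as.integer(comp[["endothelial_surface"]]),
    n_tumor_surface = as.integer(comp[["tumor_surface"]]),
    n_interstitium = as.integer(comp[["interstitium"]])
  )
  per_rule <- net$reactions %>%
    group_by(rule) %>%
    summarise(n_reactions = dplyr::n(), .groups = "drop")
  list(counts = counts, per_rule = per_rule)
}

#' Species table of a network
#' @param net An `angio_network`.
#' @return Tibble with `index`, `id`, `compartment`, `n_monomers`, `init`.
#' @export
species_table <- function(net) {
  tibble(index = seq_along(net$ids), id = net$ids,
         compartment = net$compartment,
         n_monomers = vapply(net$species, cpx_size, integer(1)),
         init = net$init)
}

#' Reaction table of a network
#' @param net An `angio_network`.
#' @return Tibble with reactant/product canonical ids and rate names.
#' @export
reaction_table <- function(net) {
  rx <- net$reactions
  tibble(
    rule = rx$rule,
    reactant1 = ifelse(is.na(rx$reactant1), NA_character_, net$ids[rx$reactant1]),
    reactant2 = ifelse(is.na(rx$reactant2), NA_character_, net$ids[rx$reactant2]),
    products = vapply(rx$products, function(p) paste(net$ids[p], collapse = " + "),
                      character(1)),
    rate = rx$rate,
    mult = rx$mult
  )
}

#' Build a network from explicit species/reaction tables
#'
#' Dual-mode input for the simulator: a pre-expanded explicit reaction list
#' (for example a transcribed equation set) can be simulated without the rule
#' engine. Species are opaque here (no site-graph structure), so profile
#' categorization is unavailable; ODE assembly and simulation work as usual.
#'
#' @param species Tibble with columns `id`, `compartment`, `init`.
#' @param reactions Tibble with columns `rule`, `reactant1`, `reactant2`
#'   (ids or NA), `products` (ids separated by `" + "`, or ""), `rate`,
#'   `mult`.
#' @return An `angio_network` with `species` set to `NULL`.
#' @export
network_from_tables <- function(species, reactions) {
  ids <- species$id
  look <- stats::setNames(seq_along(ids), ids)
  to_idx <- function(x) ifelse(is.na(x) | x == "", NA_integer_, look[x])
  prods <- lapply(reactions$products, function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    unname(look[strsplit(s, " + ", fixed = TRUE)[[1L]]])
  })
  if (any(is.na(unlist(prods)))) abort("reaction references unknown species id")
  rx <- tibble(
    rule = reactions$rule,
    reactant1 = as.integer(to_idx(reactions$reactant1)),
    reactant2 = as.integer(to_idx(reactions$reactant2)),
    products = prods,
    rate = reactions$rate,
    mult = reactions$mult %||% rep(1, nrow(reactions))
  )
  structure(list(ids = ids, species = NULL,
                 compartment = species$compartment,
                 init = species$init, reactions = rx, spec = NULL),
            class = "angio_network")
}
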