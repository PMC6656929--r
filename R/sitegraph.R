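#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup bind_rows left_join across
NULL

# ---- compartments -----------------------------------------------------------

#' Compartment tags of the tumor-tissue model
#'
#' The tissue is divided into three well-mixed regions: the endothelial cell
#' surface, the tumor cell surface, and the interstitium (which aggregates the
#' extracellular matrix and both basement membranes). Every species carries
#' exactly one tag; surface complexes carry the tag of the surface their
#' receptor or cHSPG anchor sits on.
#'
#' @return Character vector of the three compartment names.
#' @export
compartments <- function() {
  c("endothelial_surface", "tumor_surface", "interstitium")
}

surface_tags <- function() c("endothelial_surface", "tumor_surface")

# ---- monomer types ----------------------------------------------------------

#' Declare a monomer type
#'
#' A monomer is a molecule (ligand, receptor, proteoglycan, protease) with a
#' set of named binding sites. Each site can hold at most one bond.
#'
#' @param name Identifier, e.g. `"V165"` or `"VEGFR2"`.
#' @param sites Character vector of site names (may be empty for inert
#'   species such as cleaved VEGF114).
#' @param mobility One of `"soluble"`, `"surface_fixed"`, `"matrix_fixed"`.
#' @return An object of class `angio_monomer`.
#' @export
monomer <- function(name, sites = character(), mobility = "soluble") {
  stopifnot(is.character(name), length(name) == 1L)
  sites <- as.character(sites)
  if (anyDuplicated(sites)) {
    abort(paste0("duplicate site names in monomer '", name, "'"))
  }
  if (!mobility %in% c("soluble", "surface_fixed", "matrix_fixed")) {
    abort(paste0("unknown mobility '", mobility, "' for monomer '", name, "'"))
  }
  structure(list(name = name, sites = sites, mobility = mobility),
            class = "angio_monomer")
}

#' @export
print.angio_monomer <- function(x, ...) {
  cat(sprintf("<monomer> %s(%s) [%s]\n", x$name,
              paste(x$sites, collapse = ","), x$mobility))
  invisible(x)
}

# ---- species complexes ------------------------------------------------------

#' Build a concrete species complex
#'
#' A species is a connected site-graph: a multiset of monomer instances plus a
#' list of bonds between specific sites, tagged with the compartment it lives
#' in. Bonds are given as `c(i, "site_i", j, "site_j")` with 1-based instance
#' indices.
#'
#' @param types Character vector of monomer type names, one per instance.
#' @param bonds List of length-4 vectors `(i, site_i, j, site_j)`.
#' @param compartment One of [compartments()].
#' @param monomers Named list of `angio_monomer` declarations used to validate
#'   sites (optional; validation is skipped when `NULL`).
#' @return An object of class `angio_complex`.
#' @export
complex_new <- function(types, bonds = list(), compartment = "interstitium",
                        monomers = NULL) {
  n <- length(types)
  if (!compartment %in% compartments()) {
    abort(paste0("unknown compartment '", compartment, "'"))
  }
  nbr <- vector("list", n)
  for (i in seq_len(n)) nbr[[i]] <- list()
  for (b in bonds) {
    i <- as.integer(b[[1]]); si <- as.character(b[[2]])
    j <- as.integer(b[[3]]); sj <- as.character(b[[4]])
    if (i < 1L || i > n || j < 1L || j > n) abort("bond references missing instance")
    if (!is.null(monomers)) {
      if (!si %in% monomers[[types[i]]]$sites)
        abort(paste0("monomer '", types[i], "' has no site '", si, "'"))
      if (!sj %in% monomers[[types[j]]]$sites)
        abort(paste0("monomer '", types[j], "' has no site '", sj, "'"))
    }
    if (!is.null(nbr[[i]][[si]]) || !is.null(nbr[[j]][[sj]])) {
      abort("site already bonded: each site holds at most one bond")
    }
    nbr[[i]][[si]] <- list(j = j, site = sj)
    nbr[[j]][[sj]] <- list(j = i, site = si)
  }
  cpx <- structure(list(types = as.character(types), nbr = nbr,
                        compartment = compartment),
                   class = "angio_complex")
  cpx
}

cpx_size <- function(cpx) length(cpx$types)

cpx_bonds <- function(cpx) {
  out <- list()
  n <- cpx_size(cpx)
  for (i in seq_len(n)) {
    for (si in names(cpx$nbr[[i]])) {
      p <- cpx$nbr[[i]][[si]]
      if (!is.null(p) && (p$j > i || (p$j == i && p$site > si))) {
        out[[length(out) + 1L]] <- list(i = i, si = si, j = p$j, sj = p$site)
      }
    }
  }
  out
}

cpx_connected <- function(cpx) {
  n <- cpx_size(cpx)
  if (n <= 1L) return(TRUE)
  seen <- logical(n); seen[1L] <- TRUE; stack <- 1L
  while (length(stack)) {
    i <- stack[[1L]]; stack <- stack[-1L]
    for (p in cpx$nbr[[i]]) {
      if (!is.null(p) && !seen[p$j]) { seen[p$j] <- TRUE; stack <- c(stack, p$j) }
    }
  }
  all(seen)
}

# connected components as list of instance-index vectors
cpx_components <- function(cpx) {
  n <- cpx_size(cpx)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    comp[s] <- k; stack <- s
    while (length(stack)) {
      i <- stack[[1L]]; stack <- stack[-1L]
      for (p in cpx$nbr[[i]]) {
        if (!is.null(p) && comp[p$j] == 0L) { comp[p$j] <- k; stack <- c(stack, p$j) }
      }
    }
  }
  split(seq_len(n), comp)
}

# extract the sub-complex induced by instance indices (bonds leaving the set
# are dropped); compartment recomputed from mobilities when monomers given
cpx_induce <- function(cpx, idx, monomers, parent_compartment = cpx$compartment) {
  map <- integer(cpx_size(cpx)); map[idx] <- seq_along(idx)
  bonds <- list()
  for (b in cpx_bonds(cpx)) {
    if (b$i %in% idx && b$j %in% idx) {
      bonds[[length(bonds) + 1L]] <- list(map[b$i], b$si, map[b$j], b$sj)
    }
  }
  types <- cpx$types[idx]
  comp <- species_compartment(types, monomers, parent_compartment)
  complex_new(types, bonds, comp, monomers)
}

# compartment a set of monomer types must live in: any surface-fixed monomer
# pins the species to its parent surface; matrix-fixed or all-soluble ->
# interstitium
species_compartment <- function(types, monomers, parent_compartment) {
  mob <- vapply(types, function(t) monomers[[t]]$mobility, character(1))
  if (any(mob == "surface_fixed")) {
    if (!parent_compartment %in% surface_tags()) {
      abort("surface-fixed monomer outside a surface compartment")
    }
    parent_compartment
  } else {
    "interstitium"
  }
}

# ---- canonical labeling -----------------------------------------------------

perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# isomorphism-invariant vertex colors by iterative partition refinement:
# start from (type, local site states) and fold in neighbor colors until
# stable. Instances with distinct colors can be ordered outright; only
# residual symmetric groups need permutation enumeration.
refine_colors <- function(cpx) {
  n <- cpx_size(cpx)
  col <- vapply(seq_len(n), function(i) {
    sites <- sort(names(cpx$nbr[[i]]))
    loc <- vapply(sites, function(s) {
      p <- cpx$nbr[[i]][[s]]
      if (is.null(p)) paste0(s, ":free") else paste0(s, ":", cpx$types[[p$j]], ".", p$site)
    }, character(1))
    paste(cpx$types[[i]], paste(loc, collapse = ","))
  }, character(1))
  for (iter in seq_len(n)) {
    nxt <- vapply(seq_len(n), function(i) {
      sites <- sort(names(cpx$nbr[[i]]))
      nb <- vapply(sites, function(s) {
        p <- cpx$nbr[[i]][[s]]
        if (is.null(p)) "." else col[[p$j]]
      }, character(1))
      paste(col[[i]], paste(nb, collapse = "|"))
    }, character(1))
    nxt <- as.character(match(nxt, sort(unique(nxt))))
    if (length(unique(nxt)) == length(unique(col))) { col <- nxt; break }
    col <- nxt
  }
  col
}

# all orderings compatible with sorting instances by (type, refined color):
# permutations within residual groups of identical color
type_orderings <- function(types, cpx = NULL) {
  key <- if (is.null(cpx)) types else paste(types, refine_colors(cpx))
  ord <- order(key, method = "radix")
  groups <- split(ord, key[ord])
  parts <- lapply(groups, function(g) {
    lapply(perms(length(g)), function(p) g[p])
  })
  out <- list(integer(0))
  for (part in parts) {
    nxt <- list()
    for (head in out) for (tail in part) nxt[[length(nxt) + 1L]] <- c(head, tail)
    out <- nxt
  }
  out
}

render_ordering <- function(cpx, ord) {
  pos <- integer(cpx_size(cpx)); pos[ord] <- seq_along(ord)
  lab <- new.env(parent = emptyenv()); nlab <- 0L
  parts <- character(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[[k]]
    sites <- names(cpx$nbr[[i]])
    sdesc <- character(0)
    for (si in sort(sites)) {
      p <- cpx$nbr[[i]][[si]]
      if (is.null(p)) next
      key <- if (pos[i] < pos[p$j] || (pos[i] == pos[p$j] && si < p$site)) {
        paste(pos[i], si, pos[p$j], p$site)
      } else {
        paste(pos[p$j], p$site, pos[i], si)
      }
      if (is.null(lab[[key]])) { nlab <- nlab + 1L; lab[[key]] <- nlab }
      sdesc <- c(sdesc, paste0(si, "!", lab[[key]]))
    }
    parts[[k]] <- paste0(cpx$types[[i]],
                         if (length(sdesc)) paste0("(", paste(sdesc, collapse = ","), ")") else "")
  }
  paste0(paste(parts, collapse = "."), "@", cpx$compartment)
}

#' Canonical identifier of a species complex
#'
#' Two complexes receive the same string if and only if they are isomorphic:
#' same monomer multiset, same bond topology, same compartment. Complexes in
#' this model are small (at most eight monomers), so canonicalization
#' enumerates the orderings compatible with type-sorted instances and keeps
#' the lexicographically smallest rendering.
#'
#' @param cpx An `angio_complex`.
#' @return A single string, stable across sessions.
#' @export
canonical_form <- function(cpx) {
  if (!cpx_connected(cpx)) abort("canonical_form: complex is not connected")
  n <- cpx_size(cpx)
  if (n == 1L) return(render_ordering(cpx, 1L))
  # skip permutations when all types are distinct
  if (!anyDuplicated(cpx$types)) {
    return(render_ordering(cpx, order(cpx$types)))
  }
  min(vapply(type_orderings(cpx$types, cpx), function(ord) render_ordering(cpx, ord),
             character(1)))
}

#' @export
print.angio_complex <- function(x, ...) {
  cat("<species>", canonical_form(x), "\n")
  invisible(x)
}

# multiset of monomer type counts, used as a fast pre-filter during matching
cpx_type_counts <- function(cpx) table(cpx$types)
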