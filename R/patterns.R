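# Pattern language for reaction rules.
#
# A pattern is a partial complex: monomer instances with per-site conditions
# plus internal pattern bonds. Site conditions:
#   (absent)      unspecified; the site may be free or bound
#   "free"        the site must be unbonded
#   "bound"       the site must be bonded to anything
#   "TYPE:site"   the site must be bonded to site `site` of a TYPE monomer
# Sites participating in an internal pattern bond are checked structurally.
# The compartment condition is NA (any), "surface" (either cell surface),
# or a specific compartment tag.

#' Build a rule pattern
#'
#' @param types Character vector of monomer type names.
#' @param cond List (one element per instance) of named character vectors of
#'   site conditions; use `NULL` for "no conditions".
#' @param bonds List of internal pattern bonds `c(i, site_i, j, site_j)`.
#' @param comp Compartment condition: `NA`, `"surface"`, or a tag.
#' @return An object of class `angio_pattern`.
#' @export
pattern <- function(types, cond = NULL, bonds = list(), comp = NA_character_) {
  n <- length(types)
  if (is.null(cond)) cond <- vector("list", n)
  stopifnot(length(cond) == n)
  pb <- lapply(bonds, function(b) {
    list(i = as.integer(b[[1]]), si = as.character(b[[2]]),
         j = as.integer(b[[3]]), sj = as.character(b[[4]]))
  })
  structure(list(types = as.character(types), cond = cond, pbonds = pb,
                 comp = comp),
            class = "angio_pattern")
}

#' Single-monomer pattern shorthand
#'
#' `P1("V165", n = "free")` is `pattern("V165", cond = list(c(n = "free")))`.
#'
#' @param type Monomer type name.
#' @param ... Named site conditions.
#' @param comp Compartment condition.
#' @return An `angio_pattern`.
#' @export
P1 <- function(type, ..., comp = NA_character_) {
  cnd <- c(...)
  pattern(type, cond = list(cnd), comp = comp)
}

pat_size <- function(pat) length(pat$types)

comp_matches <- function(cond, tag) {
  if (is.na(cond)) return(TRUE)
  if (identical(cond, "surface")) return(tag %in% surface_tags())
  identical(cond, tag)
}

site_cond_ok <- function(cpx, i, site, cond) {
  p <- cpx$nbr[[i]][[site]]
  if (identical(cond, "free")) return(is.null(p))
  if (identical(cond, "bound")) return(!is.null(p))
  # typed half-bond "TYPE:site"
  if (is.null(p)) return(FALSE)
  ts <- strsplit(cond, ":", fixed = TRUE)[[1]]
  identical(cpx$types[[p$j]], ts[[1]]) && identical(p$site, ts[[2]])
}

# All injective embeddings of `pat` into `cpx`. Returns a list of integer
# vectors (pattern instance -> species instance). Patterns here have at most
# three monomers, species at most eight, so plain backtracking is fine.
match_pattern <- function(pat, cpx) {
  if (!comp_matches(pat$comp, cpx$compartment)) return(list())
  np <- pat_size(pat); nc <- cpx_size(cpx)
  if (np > nc) return(list())
  # candidate species instances per pattern instance
  cand <- vector("list", np)
  for (k in seq_len(np)) {
    ok <- which(cpx$types == pat$types[[k]])
    cnd <- pat$cond[[k]]
    if (length(cnd)) {
      keep <- vapply(ok, function(i) {
        all(vapply(names(cnd), function(s) site_cond_ok(cpx, i, s, cnd[[s]]),
                   logical(1)))
      }, logical(1))
      ok <- ok[keep]
    }
    if (!length(ok)) return(list())
    cand[[k]] <- ok
  }
  out <- list()
  assign_next <- function(k, used, map) {
    if (k > np) {
      for (b in pat$pbonds) {
        p <- cpx$nbr[[map[b$i]]][[b$si]]
        if (is.null(p) || p$j != map[b$j] || !identical(p$site, b$sj)) return()
      }
      out[[length(out) + 1L]] <<- map
      return()
    }
    for (i in cand[[k]]) {
      if (i %in% used) next
      map[k] <- i
      assign_next(k + 1L, c(used, i), map)
    }
  }
  assign_next(1L, integer(0), integer(np))
  out
}

# does the pattern match the *whole* species exactly (used by degradation and
# conversion rules, which consume entire species)?
match_whole <- function(pat, cpx) {
  if (pat_size(pat) != cpx_size(cpx)) return(list())
  match_pattern(pat, cpx)
}
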