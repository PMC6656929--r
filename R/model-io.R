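# Structured-text (YAML) serialization of model specifications and geometry.

pattern_to_list <- function(pat) {
  list(types = as.list(pat$types),
       cond = lapply(pat$cond, function(cn) if (is.null(cn)) list() else as.list(cn)),
       bonds = lapply(pat$pbonds, function(b) list(b$i, b$si, b$j, b$sj)),
       comp = if (is.na(pat$comp)) NULL else pat$comp)
}

pattern_from_list <- function(x) {
  pattern(unlist(x$types),
          cond = lapply(x$cond, function(cn) {
            if (!length(cn)) NULL else unlist(cn)
          }),
          bonds = x$bonds,
          comp = x$comp %||% NA_character_)
}

complex_to_list <- function(cpx) {
  list(types = as.list(cpx$types),
       bonds = lapply(cpx_bonds(cpx), function(b) list(b$i, b$si, b$j, b$sj)),
       compartment = cpx$compartment)
}

complex_from_list <- function(x, monomers) {
  complex_new(unlist(x$types), x$bonds, x$compartment, monomers)
}

#' Write a model specification to a YAML file
#'
#' The documented schema has four sections: `monomers` (name, sites,
#' mobility), `compartments`, `seeds` (complex + initial-amount reference)
#' and `rules` (class, reactant patterns, payloads, rate names).
#'
#' @param spec An `angio_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  doc <- list(
    name = spec$name,
    compartments = as.list(compartments()),
    monomers = lapply(unname(spec$monomers), function(m) {
      list(name = m$name, sites = as.list(m$sites), mobility = m$mobility)
    }),
    seeds = lapply(spec$seeds, function(sd) {
      c(complex_to_list(sd$complex), list(init = sd$init %||% "zero"))
    }),
    rules = lapply(unname(spec$rules), function(r) {
      list(id = r$id, class = r$class,
           reactants = lapply(r$reactants, pattern_to_list),
           rate_fwd = r$rate_fwd,
           rate_rev = if (is.na(r$rate_rev)) NULL else r$rate_rev,
           bond = r$bond,
           delbond = r$delbond,
           products = if (is.null(r$products)) NULL else
             lapply(r$products, complex_to_list),
           conversion = if (is.null(r$conversion)) NULL else as.list(r$conversion),
           notes = r$notes)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a model specification from a YAML file
#'
#' @param path File written by [write_model_spec()] (or hand-authored in the
#'   same schema).
#' @param validate Run structural validation (default TRUE).
#' @return An `angio_model`.
#' @export
load_model_spec <- function(path, validate = TRUE) {
  doc <- yaml::read_yaml(path)
  monomers <- lapply(doc$monomers, function(m) {
    if (is.null(m$name) || is.null(m$mobility)) {
      abort("model file: monomer entry missing 'name' or 'mobility'")
    }
    monomer(m$name, unlist(m$sites) %||% character(), m$mobility)
  })
  names(monomers) <- vapply(monomers, function(m) m$name, character(1))
  seeds <- lapply(doc$seeds, function(sd) {
    list(complex = complex_from_list(sd, monomers), init = sd$init %||% "zero")
  })
  rules <- lapply(doc$rules, function(r) {
    if (is.null(r$class) || !r$class %in% rule_classes()) {
      abort(paste0("model file: unknown rule_class '", r$class %||% "<missing>",
                   "' in rule '", r$id %||% "?", "'"))
    }
    rule(r$id, r$class,
         reactants = lapply(r$reactants, pattern_from_list),
         rate_fwd = r$rate_fwd,
         rate_rev = r$rate_rev %||% NA_character_,
         bond = r$bond,
         delbond = r$delbond,
         products = if (is.null(r$products)) NULL else
           lapply(r$products, complex_from_list, monomers = monomers),
         conversion = if (is.null(r$conversion)) NULL else unlist(r$conversion),
         notes = r$notes %||% "")
  })
  spec <- model_spec(monomers, seeds, rules, name = doc$name %||% "model")
  if (validate) assert_valid_spec(spec)
  spec
}

#' Write geometry to a YAML file
#' @param geom An `angio_geometry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(unclass(geom), path)
  invisible(path)
}

#' Load geometry from a YAML file
#' @param path YAML file with the [geometry()] fields.
#' @return An `angio_geometry`.
#' @export
load_geometry <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(geometry, doc)
}

# ---- shipped copies ---------------------------------------------------------

#' Paths of the shipped model, parameter and geometry files
#' @return Named character vector with `model`, `parameters`, `geometry`.
#' @export
angionet_files <- function() {
  c(model = system.file("extdata", "angionet_model.yaml", package = "angionet"),
    parameters = system.file("extdata", "angionet_parameters.yaml", package = "angionet"),
    geometry = system.file("extdata", "angionet_geometry.yaml", package = "angionet"))
}
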