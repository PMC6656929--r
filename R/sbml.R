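# SBML Level 3 export of an expanded network (species, compartments,
# parameters and mass-action kinetic laws), plus result writing with a
# reproducibility manifest.

sbml_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", x), x, paste0("s_", x))
}

#' Export a reaction network as an SBML Level 3 document
#'
#' Writes species (with compartment assignment and initial amounts),
#' the three tissue compartments, the resolved rate parameters and one
#' reaction per network reaction with a mass-action kinetic law.
#'
#' @param net An `angio_network`.
#' @param params An `angio_params`.
#' @param path Output file.
#' @param geom An `angio_geometry` (for initial amounts).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(net, params, path, geom = geometry()) {
  rates <- param_rates(params)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = "http://www.sbml.org/sbml/level3/version2/core",
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "angionet")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cn in compartments()) {
    xml2::xml_add_child(comps, "compartment", id = sbml_id(cn), constant = "true")
  }

  x0 <- resolve_init(net$init, params, geom)
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_along(net$ids)) {
    xml2::xml_add_child(sps, "species",
                        id = sbml_id(net$ids[[i]]),
                        name = net$ids[[i]],
                        compartment = sbml_id(net$compartment[[i]]),
                        initialAmount = format(x0[[i]], digits = 12),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_len(nrow(rates))) {
    xml2::xml_add_child(pars, "parameter", id = sbml_id(rates$name[[i]]),
                        value = format(rates$value[[i]], digits = 12),
                        constant = "true")
  }

  rxs <- xml2::xml_add_child(model, "listOfReactions")
  rx <- net$reactions
  for (j in seq_len(nrow(rx))) {
    rn <- xml2::xml_add_child(rxs, "reaction", id = paste0("r", j),
                              name = rx$rule[[j]], reversible = "false")
    reac <- stats::na.omit(c(rx$reactant1[[j]], rx$reactant2[[j]]))
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in reac) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sbml_id(net$ids[[s]]),
                            stoichiometry = "1", constant = "true")
      }
    }
    if (length(rx$products[[j]])) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in rx$products[[j]]) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sbml_id(net$ids[[s]]),
                            stoichiometry = "1", constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    terms <- c(sbml_id(rx$rate[[j]]), sbml_id(net$ids[reac]))
    if (length(terms) == 1L) {
      xml2::xml_add_child(math, "ci", terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (tm in terms) xml2::xml_add_child(ap, "ci", tm)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Count species and reactions in an SBML document
#' @param path SBML file.
#' @return List with `n_species`, `n_reactions`, `n_compartments`.
#' @export
sbml_counts <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  list(
    n_species = length(xml2::xml_find_all(doc, "//sbml:species", ns)),
    n_reactions = length(xml2::xml_find_all(doc, "//sbml:reaction", ns)),
    n_compartments = length(xml2::xml_find_all(doc, "//sbml:compartment", ns))
  )
}

# ---- result writing ---------------------------------------------------------

#' Write result tables with a reproducibility manifest
#'
#' Writes each named tibble as an RFC-4180 CSV ('.' decimal separator, UTF-8)
#' and a `manifest.json` recording file names, row counts, a content hash of
#' the configuration, the seed, and package/R versions. Same config + seed
#' reproduce byte-identical CSVs.
#'
#' @param results Named list of data frames.
#' @param outdir Output directory (created if missing).
#' @param config List describing the run configuration (hashed into the
#'   manifest).
#' @param seed Integer seed used by the run (or `NULL`).
#' @return Path of the manifest, invisibly.
#' @export
write_results <- function(results, outdir, config = list(), seed = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stopifnot(length(results) == 0 || !is.null(names(results)))
  files <- character(0)
  for (nm in names(results)) {
    fp <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], fp, row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, basename(fp))
  }
  manifest <- list(
    files = as.list(files),
    rows = lapply(results, nrow),
    config_hash = rlang::hash(config),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = tryCatch(as.character(utils::packageVersion("angionet")),
                               error = function(e) "dev")
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
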