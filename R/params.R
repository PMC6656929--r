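# Kinetic, density and production/degradation parameters, and the derivation
# rules that turn measured affinities and half-lives into rate constants.
#
# Units throughout: kon and catalytic constants in 1/(M s); koff, kdeg, kint
# in 1/s; Kd in M; production in molecules/cell/s (per cell type) or
# molecules/cm^3 tissue/s (the generic PF4 source); receptor densities in
# copies/cell; iHSPG in sites/cm^3 tissue.

AVOGADRO <- 6.02214076e23

#' Dissociation rate from an affinity
#'
#' `koff = Kd * kon`; how printed Kd values are turned into dissociation
#' rates at a fixed association rate.
#'
#' @param kd Dissociation constant (M).
#' @param kon Association rate (1/(M s)).
#' @return Dissociation rate (1/s).
#' @export
koff_from_kd <- function(kd, kon) {
  if (any(kd < 0) || any(kon <= 0)) abort("koff_from_kd: Kd must be >= 0 and kon > 0")
  kd * kon
}

#' First-order degradation rate from a half-life
#'
#' @param t_half Half-life in seconds (> 0).
#' @return `ln(2) / t_half` in 1/s.
#' @export
kdeg_from_half_life <- function(t_half) {
  if (any(t_half <= 0)) abort("kdeg_from_half_life: half-life must be > 0")
  log(2) / t_half
}

#' Qualitative expression level to receptor density
#'
#' Maps the qualitative low/medium/high expression convention to
#' 2500/5000/10000 receptors per cell.
#'
#' @param level Character vector of `"low"`, `"medium"`, `"high"`.
#' @return Receptors per cell.
#' @export
expression_level_density <- function(level) {
  map <- c(low = 2500, medium = 5000, high = 10000)
  bad <- setdiff(level, names(map))
  if (length(bad)) abort(paste0("unknown expression level: ", paste(bad, collapse = ", ")))
  unname(map[level])
}

#' Derive cHSPG binding parameters from relative heparin affinities
#'
#' All factors share FGF2's cHSPG association rate; dissociation rates are
#' scaled by each factor's heparin Kd relative to FGF2's, so the measured
#' heparin affinity order (PF4 > FGF2 > TSP1 > V165) carries over to cHSPG.
#'
#' @param heparin_kd Named numeric (M) with entries for at least `FGF2`;
#'   defaults to the measured V165/FGF2/TSP1/PF4 values (80/39/41/20 nM).
#' @param fgf2_chspg List with `kon`, `koff` for the FGF2-cHSPG pair.
#' @return Named list factor -> list(kon, koff, Kd).
#' @export
derive_chspg_rates <- function(heparin_kd = c(V165 = 80e-9, FGF2 = 39e-9,
                                              TSP1 = 41e-9, PF4 = 20e-9),
                               fgf2_chspg = list(kon = 5e5, koff = koff_from_kd(39e-9, 5e5))) {
  if (!"FGF2" %in% names(heparin_kd)) abort("derive_chspg_rates: missing FGF2 reference")
  if (any(heparin_kd <= 0)) abort("derive_chspg_rates: heparin Kd values must be positive")
  ref <- heparin_kd[["FGF2"]]
  out <- lapply(names(heparin_kd), function(f) {
    koff <- fgf2_chspg$koff * heparin_kd[[f]] / ref
    list(kon = fgf2_chspg$kon, koff = koff, Kd = koff / fgf2_chspg$kon)
  })
  stats::setNames(out, names(heparin_kd))
}

#' Apply the VEGF-axis fold-scaling rules
#'
#' Derives the scaled VEGF-axis rates from their reference pairs, as koff
#' scalings at fixed kon: V165-NRP1 alone is 20-fold weaker than
#' V165-NRP1:cHSPG; the V165-synergistic NRP1-cHSPG coupling is 10-fold
#' stronger than bare NRP1-cHSPG; VEGFR1-NRP1 coupling is 10-fold weaker than
#' VEGFR2-NRP1; VEGFR1-cHSPG coupling is 5-fold stronger than NRP1-cHSPG.
#' Single-shot: applying it to an already-scaled set is an error.
#'
#' @param base Named list of binding entries (`list(kon, koff)`) containing
#'   the reference pairs `v_n_hspg`, `c_vr2_n_hspg`, `c_n_h`.
#' @return `base` extended with `v_n_alone`, `c_vr2_n_alone`, `c_vn_h`,
#'   `c_r1_n`, `c_r1_h`; attribute `fold_scaled` set.
#' @export
apply_fold_scalings <- function(base) {
  if (isTRUE(attr(base, "fold_scaled"))) {
    abort("apply_fold_scalings: scalings already applied (single-shot)")
  }
  need <- c("v_n_hspg", "c_vr2_n_hspg", "c_n_h")
  miss <- setdiff(need, names(base))
  if (length(miss)) abort(paste0("apply_fold_scalings: missing reference rate ",
                                 paste(miss, collapse = ", ")))
  scale_koff <- function(entry, fold) list(kon = entry$kon, koff = entry$koff * fold)
  base$v_n_alone <- scale_koff(base$v_n_hspg, 20)        # 20-fold weaker
  base$c_vr2_n_alone <- scale_koff(base$c_vr2_n_hspg, 20)
  base$c_vn_h <- scale_koff(base$c_n_h, 1 / 10)          # 10x stronger
  base$c_r1_n <- scale_koff(base$c_n_h, 10)              # VEGFR1-NRP1 10x weaker than VEGFR2-NRP1
  base$c_r1_h <- scale_koff(base$c_n_h, 1 / 5)           # 5x stronger than NRP1-cHSPG
  attr(base, "fold_scaled") <- TRUE
  base
}

#' Default parameter set of the builtin model
#'
#' Main-text values (PF4-axis and factor-factor affinities, heparin Kd
#' scalings, half-lives, the CXCR3 density, the fold-scaling rules and the
#' association rate convention of 5e5 1/(M s)) are encoded directly. All
#' remaining kinetics and densities are placeholder transcriptions in the
#' style of the prior compartmental models this model family builds on; they
#' are marked `provenance = "placeholder"` in the parameter file and the
#' baseline production rates are re-tuned against the measured tissue
#' concentration table by [calibrate_baseline()].
#'
#' @return An object of class `angio_params`.
#' @export
default_parameters <- function() {
  kon5 <- 5e5

  ch <- derive_chspg_rates()
  ih_kd <- c(V165 = 80e-9, FGF2 = 39e-9, TSP1 = 41e-9, PF4 = 20e-9)

  binding <- list(
    # VEGF axis (prior-model style placeholders; fold-scaled below)
    v165_r2 = list(kon = 1e7, koff = 5e-4),
    v121_r2 = list(kon = 1e7, koff = 5e-4),
    v165_r1 = list(kon = 3e7, koff = 5e-4),
    v121_r1 = list(kon = 3e7, koff = 5e-4),
    v_n_hspg = list(kon = 3.2e6, koff = 1e-3),
    c_r2_vn = list(kon = 1e7, koff = 1e-3),
    c_r2_vh = list(kon = 1e7, koff = 1e-3),
    c_vr2_n_hspg = list(kon = 3.2e6, koff = 1e-3),
    c_n_h = list(kon = 1e7, koff = 1e-3),
    # direct V165-cHSPG and its VEGFR2-bound coupling variant
    v_ch = ch$V165[c("kon", "koff")],
    c_vr2_h = ch$V165[c("kon", "koff")],
    # TSP1 axis
    t_cd36 = list(kon = kon5, koff = koff_from_kd(40e-9, kon5)),
    t_cd47 = list(kon = kon5, koff = koff_from_kd(40e-9, kon5)),
    t_lrp1 = list(kon = kon5, koff = koff_from_kd(17e-9, kon5)),
    t_b1 = list(kon = kon5, koff = koff_from_kd(80e-9, kon5)),
    t_ch = ch$TSP1[c("kon", "koff")],
    c_tr_r2 = list(kon = 1e7, koff = 1e-3),
    # FGF2 axis
    f_ch = ch$FGF2[c("kon", "koff")],
    fh_r = list(kon = kon5, koff = koff_from_kd(0.3e-9, kon5)),
    f_r = list(kon = kon5, koff = koff_from_kd(40e-9, kon5)),
    c_dim = list(kon = 1e7, koff = 1e-4),
    # PF4 axis (printed Kd values at the 5e5 association-rate convention)
    p_cxcr3 = list(kon = kon5, koff = koff_from_kd(1.85e-9, kon5)),
    p_lrp1 = list(kon = kon5, koff = koff_from_kd(238e-9, kon5)),
    p_ch = ch$PF4[c("kon", "koff")],
    m9_lrp1 = list(kon = kon5, koff = koff_from_kd(50e-9, kon5)),
    # interstitial factor-factor binding (printed Kd values)
    t_v = list(kon = kon5, koff = koff_from_kd(10e-9, kon5)),
    t_f = list(kon = kon5, koff = koff_from_kd(10.8e-9, kon5)),
    p_v = list(kon = kon5, koff = koff_from_kd(5e-9, kon5)),
    p_f = list(kon = kon5, koff = koff_from_kd(37e-9, kon5)),
    # iHSPG reservoir binding: heparin Kd values used directly
    v_ih = list(kon = kon5, koff = koff_from_kd(ih_kd[["V165"]], kon5)),
    f_ih = list(kon = kon5, koff = koff_from_kd(ih_kd[["FGF2"]], kon5)),
    t_ih = list(kon = kon5, koff = koff_from_kd(ih_kd[["TSP1"]], kon5)),
    p_ih = list(kon = kon5, koff = koff_from_kd(ih_kd[["PF4"]], kon5))
  )
  binding <- apply_fold_scalings(binding)

  half_life <- c(V165 = 3600, V121 = 3600, V114 = 3600, FGF2 = 3600,
                 TSP1 = 3600, TSP1c = 3600, PF4 = 300,
                 MMP3 = 3600, proMMP9 = 3600, MMP9 = 3600)

  production <- c(
    # molecules/cell/s; baseline values are the calibrated outputs of
    # calibrate_baseline() against the measured tissue-concentration table
    q_v165_ec = 0.32154, q_v165_tc = 0.32154,
    q_v121_ec = 0.32154, q_v121_tc = 0.32154,
    q_fgf2_ec = 2.22574, q_fgf2_tc = 2.22574,
    q_tsp1_ec = 0.528693, q_tsp1_tc = 0.528693,
    q_mmp3_ec = 1.63385, q_mmp3_tc = 1.63385,
    q_prommp9_ec = 3.00638, q_prommp9_tc = 3.00638,
    # generic tissue-level PF4 source, molecules/cm^3/s
    q_pf4 = 3.0656e9
  )

  densities <- tibble(
    species = rep(c("VEGFR1", "VEGFR2", "NRP1", "FGFR1", "CD36", "CD47",
                    "LRP1", "B1", "CXCR3", "cHSPG"), times = 2),
    side = rep(c("ec", "tc"), each = 10),
    value = c(4500, 3500, 20000, 18000, 2000, 2000, 1000, 1000,
              expression_level_density("low"), 200000,
              500, 300, 15000, 18000, 2000, 2000, 1000, 1000,
              expression_level_density("low"), 200000),
    units = "receptors/cell",
    provenance = c(rep("placeholder", 8), "printed", "placeholder",
                   rep("placeholder", 8), "printed", "placeholder")
  )
  densities <- bind_rows(densities, tibble(
    species = "iHSPG", side = "matrix", value = 1.0e14,
    units = "sites/cm3", provenance = "placeholder"
  ))

  structure(list(
    binding = binding,
    unimolecular = c(koff_trimer_h = 1e-3, kint = 2.8e-4),
    catalytic = c(k_act_m9 = 450, k_cl_t = 1.2e7, k_cl_v = 7e4),
    half_life = half_life,
    production = production,
    densities = densities
  ), class = "angio_params")
}

#' @export
print.angio_params <- function(x, ...) {
  cat(sprintf("<angio_params> %d binding pairs, %d production rates, %d density entries\n",
              length(x$binding), length(x$production), nrow(x$densities)))
  invisible(x)
}

#' Flat rate table of a parameter set
#'
#' Resolves every named rate constant: `kon_<pair>` / `koff_<pair>` for the
#' binding entries, `kdeg_<species>` from half-lives, catalytic and
#' first-order extras, and production rates. The `kind` column drives unit
#' conversion during ODE assembly (`bimolecular` rates are per molar,
#' `unimolecular` per second, `production` in molecule fluxes).
#'
#' @param params An `angio_params`.
#' @return Tibble with `name`, `value`, `kind`.
#' @export
param_rates <- function(params) {
  rows <- list()
  for (nm in names(params$binding)) {
    b <- params$binding[[nm]]
    rows[[length(rows) + 1L]] <- tibble(
      name = c(paste0("kon_", nm), paste0("koff_", nm)),
      value = c(b$kon, b$koff),
      kind = c("bimolecular", "unimolecular"))
  }
  if (length(params$unimolecular)) {
    rows[[length(rows) + 1L]] <- tibble(
      name = names(params$unimolecular),
      value = unname(params$unimolecular), kind = "unimolecular")
  }
  if (length(params$catalytic)) {
    rows[[length(rows) + 1L]] <- tibble(
      name = names(params$catalytic),
      value = unname(params$catalytic), kind = "bimolecular")
  }
  if (length(params$half_life)) {
    rows[[length(rows) + 1L]] <- tibble(
      name = paste0("kdeg_", tolower(names(params$half_life))),
      value = kdeg_from_half_life(unname(params$half_life)), kind = "unimolecular")
  }
  if (length(params$production)) {
    rows[[length(rows) + 1L]] <- tibble(
      name = names(params$production),
      value = unname(params$production), kind = "production")
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(name = character(), value = numeric(), kind = character())
  }
  out
}

#' Scale production rates or densities by named multipliers
#'
#' The workhorse of the secretion scans and cHSPG sweeps: returns a modified
#' parameter set with selected production rates (e.g. `q_pf4`) or density
#' entries (e.g. `cHSPG`) multiplied by the given factors. Factor-level names
#' (`"VEGF"`, `"FGF2"`, `"TSP1"`, `"PF4"`, `"MMP3"`, `"proMMP9"`) expand to
#' all their production entries (both isoforms and both cell types for VEGF).
#'
#' @param params An `angio_params`.
#' @param production Named numeric of multipliers (factor names or `q_*`).
#' @param densities Named numeric of multipliers (species names).
#' @return Modified `angio_params`.
#' @export
scale_parameters <- function(params, production = NULL, densities = NULL) {
  if (!is.null(production)) {
    for (nm in names(production)) {
      targets <- if (nm %in% names(params$production)) nm else {
        key <- switch(nm,
                      VEGF = c("q_v165_ec", "q_v165_tc", "q_v121_ec", "q_v121_tc"),
                      FGF2 = c("q_fgf2_ec", "q_fgf2_tc"),
                      TSP1 = c("q_tsp1_ec", "q_tsp1_tc"),
                      MMP3 = c("q_mmp3_ec", "q_mmp3_tc"),
                      proMMP9 = c("q_prommp9_ec", "q_prommp9_tc"),
                      PF4 = "q_pf4",
                      abort(paste0("unknown production target '", nm, "'")))
        key
      }
      params$production[targets] <- params$production[targets] * production[[nm]]
    }
  }
  if (!is.null(densities)) {
    for (nm in names(densities)) {
      hit <- params$densities$species == nm
      if (!any(hit)) abort(paste0("unknown density species '", nm, "'"))
      params$densities$value[hit] <- params$densities$value[hit] * densities[[nm]]
    }
  }
  params
}

# ---- parameter file I/O -----------------------------------------------------

#' Write a parameter set to a YAML file
#' @param params An `angio_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  doc <- list(
    binding = lapply(params$binding, function(b) {
      list(kon = b$kon, koff = b$koff, Kd = b$koff / b$kon)
    }),
    unimolecular = as.list(params$unimolecular),
    catalytic = as.list(params$catalytic),
    half_life_s = as.list(params$half_life),
    production = as.list(params$production),
    densities = lapply(seq_len(nrow(params$densities)), function(i) {
      as.list(params$densities[i, ])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a parameter set from a YAML file
#'
#' Validates the file: every rate name used by the builtin model must
#' resolve, all densities must be nonnegative, and whenever both a Kd and a
#' (kon, koff) pair are present they must agree to 1%.
#'
#' @param path YAML file written by [write_parameters()].
#' @param check_coverage Require coverage of all builtin rate names
#'   (default TRUE).
#' @return An `angio_params`.
#' @export
load_parameters <- function(path, check_coverage = TRUE) {
  doc <- yaml::read_yaml(path)
  binding <- lapply(doc$binding, function(b) {
    if (!is.null(b$Kd)) {
      kd_implied <- b$koff / b$kon
      if (b$Kd > 0 && abs(kd_implied - b$Kd) / b$Kd > 0.01) {
        abort(paste0("inconsistent Kd vs koff/kon (", signif(b$Kd, 4), " vs ",
                     signif(kd_implied, 4), ")"))
      }
    }
    list(kon = b$kon, koff = b$koff)
  })
  attr(binding, "fold_scaled") <- TRUE  # shipped files are post-scaling
  dens <- bind_rows(lapply(doc$densities, as_tibble))
  if (any(dens$value < 0)) abort("negative density in parameter file")
  params <- structure(list(
    binding = binding,
    unimolecular = unlist(doc$unimolecular),
    catalytic = unlist(doc$catalytic),
    half_life = unlist(doc$half_life_s),
    production = unlist(doc$production),
    densities = dens
  ), class = "angio_params")
  if (check_coverage) check_param_coverage(params, builtin_model(validate = FALSE))
  params
}

#' Check that a parameter set covers every rate a model references
#' @param params An `angio_params`.
#' @param spec An `angio_model`.
#' @return Invisibly TRUE; errors with the unresolved names otherwise.
#' @export
check_param_coverage <- function(params, spec) {
  have <- param_rates(params)$name
  need <- rate_names(spec)
  miss <- setdiff(need, have)
  if (length(miss)) {
    abort(paste0("unresolved rate name(s): ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
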