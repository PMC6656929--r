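# Tumor-tissue geometry and unit conversions. Internal ODE state is in
# mol/cm^3 tissue; all reported concentrations are fluid-phase (pmol/L or
# nmol/L of interstitial fluid).

#' Tumor-tissue geometry
#'
#' @param tumor_volume_cm3 Tumor volume (default 33 cm^3 breast tumor).
#' @param interstitial_fluid_fraction Fraction of tissue volume that is
#'   available interstitial fluid (default 0.31).
#' @param cells_ec_per_cm3,cells_tc_per_cm3 Endothelial / tumor cell number
#'   densities (1/cm^3 tissue).
#' @param area_ec_cm2_per_cm3,area_tc_cm2_per_cm3 Surface-area densities
#'   (cm^2/cm^3 tissue); carried for documentation, the fluid-equivalent
#'   kinetic convention does not consume them.
#' @return Object of class `angio_geometry`.
#' @export
geometry <- function(tumor_volume_cm3 = 33,
                     interstitial_fluid_fraction = 0.31,
                     cells_ec_per_cm3 = 1e7,
                     cells_tc_per_cm3 = 1e8,
                     area_ec_cm2_per_cm3 = 70,
                     area_tc_cm2_per_cm3 = 600) {
  if (!(interstitial_fluid_fraction > 0 && interstitial_fluid_fraction < 1)) {
    abort("interstitial_fluid_fraction must be in (0, 1)")
  }
  vals <- c(tumor_volume_cm3, cells_ec_per_cm3, cells_tc_per_cm3,
            area_ec_cm2_per_cm3, area_tc_cm2_per_cm3)
  if (any(vals <= 0)) abort("geometry values must be positive")
  structure(list(
    tumor_volume_cm3 = tumor_volume_cm3,
    interstitial_fluid_fraction = interstitial_fluid_fraction,
    cells_ec_per_cm3 = cells_ec_per_cm3,
    cells_tc_per_cm3 = cells_tc_per_cm3,
    area_ec_cm2_per_cm3 = area_ec_cm2_per_cm3,
    area_tc_cm2_per_cm3 = area_tc_cm2_per_cm3
  ), class = "angio_geometry")
}

#' @export
print.angio_geometry <- function(x, ...) {
  cat(sprintf("<angio_geometry> %g cm3 tumor, fluid fraction %g, EC %g /cm3, TC %g /cm3\n",
              x$tumor_volume_cm3, x$interstitial_fluid_fraction,
              x$cells_ec_per_cm3, x$cells_tc_per_cm3))
  invisible(x)
}

#' Interstitial fluid volume in liters
#' @param geom An `angio_geometry`.
#' @return Volume of available interstitial fluid (L).
#' @export
interstitial_fluid_volume <- function(geom) {
  geom$tumor_volume_cm3 * geom$interstitial_fluid_fraction / 1000
}

#' Convert tissue concentration to fluid-phase concentration
#'
#' @param amount Concentration in mol/cm^3 tissue.
#' @param geom An `angio_geometry`.
#' @param units `"M"`, `"nM"` or `"pM"` (of interstitial fluid).
#' @return Fluid-phase concentration.
#' @export
tissue_to_fluid_concentration <- function(amount, geom, units = c("pM", "nM", "M")) {
  units <- match.arg(units)
  if (any(amount < -1e-15)) abort("negative tissue concentration")
  molar <- amount / geom$interstitial_fluid_fraction * 1000  # mol/L fluid
  switch(units, M = molar, nM = molar * 1e9, pM = molar * 1e12)
}

#' Convert fluid-phase molar concentration to tissue units
#' @param molar Concentration in mol/L interstitial fluid.
#' @param geom An `angio_geometry`.
#' @return mol/cm^3 tissue.
#' @export
fluid_to_tissue_concentration <- function(molar, geom) {
  molar * geom$interstitial_fluid_fraction / 1000
}

#' Receptor copy number to tissue concentration
#' @param count Receptors per cell.
#' @param cells Cells per cm^3 tissue.
#' @return mol/cm^3 tissue.
#' @export
receptors_per_cell_to_tissue_conc <- function(count, cells) {
  if (any(count < 0) || any(cells < 0)) abort("counts must be nonnegative")
  count * cells / AVOGADRO
}

#' A controlled-release depot dose
#' @param mass_mg Dose mass (mg).
#' @param molecular_weight Molar mass (g/mol); PF4 is modeled at 7.78 kDa.
#' @param release_rate_constant First-order release constant (1/s).
#' @return Object of class `angio_dose`.
#' @export
dose <- function(mass_mg = 5, molecular_weight = 7780,
                 release_rate_constant = 2.8e-5) {
  if (any(c(mass_mg, molecular_weight, release_rate_constant) < 0)) {
    abort("dose fields must be nonnegative")
  }
  structure(list(mass_mg = mass_mg, molecular_weight = molecular_weight,
                 release_rate_constant = release_rate_constant),
            class = "angio_dose")
}

#' Moles of drug in a depot dose
#' @param d An `angio_dose`.
#' @return Amount in mol.
#' @export
dose_to_moles <- function(d) {
  d$mass_mg / 1000 / d$molecular_weight
}
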