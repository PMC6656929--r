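test_that("interstitial fluid volume is tumor volume times fluid fraction", {
  expect_equal(interstitial_fluid_volume(geometry()), 33 * 0.31 / 1000)
  expect_equal(interstitial_fluid_volume(
    geometry(tumor_volume_cm3 = 1, interstitial_fluid_fraction = 0.5)), 5e-4)
  expect_error(geometry(interstitial_fluid_fraction = 0))
  expect_error(geometry(interstitial_fluid_fraction = 1))
})

test_that("tissue to fluid conversion is dimensionally correct and invertible", {
  g <- geometry()
  expect_identical(tissue_to_fluid_concentration(0, g, "pM"), 0)
  # 3.1e-18 mol/cm^3 tissue at fluid fraction 0.31 -> 1e-14 mol/L fluid
  expect_equal(tissue_to_fluid_concentration(3.1e-18, g, "M"), 1e-14)
  expect_equal(tissue_to_fluid_concentration(3.1e-18, g, "pM"), 0.01)
  g2 <- geometry(interstitial_fluid_fraction = 0.62)
  expect_equal(tissue_to_fluid_concentration(3.1e-18, g2, "pM"),
               tissue_to_fluid_concentration(3.1e-18, g, "pM") / 2)
  # round trip to 1e-12 relative
  x <- 4.2e-13
  back <- fluid_to_tissue_concentration(
    tissue_to_fluid_concentration(x, g, "M"), g)
  expect_lt(abs(back - x) / x, 1e-12)
})

test_that("receptor densities convert linearly to tissue concentrations", {
  expect_equal(receptors_per_cell_to_tissue_conc(2500, 1e8), 4.151e-13,
               tolerance = 1e-3)
  expect_identical(receptors_per_cell_to_tissue_conc(0, 1e8), 0)
  expect_equal(receptors_per_cell_to_tissue_conc(5000, 2e8),
               4 * receptors_per_cell_to_tissue_conc(2500, 1e8))
  expect_error(receptors_per_cell_to_tissue_conc(-1, 1e8))
})

test_that("depot doses convert mass to moles", {
  expect_equal(dose_to_moles(dose(5, 7780)), 5e-3 / 7780)
  expect_equal(dose_to_moles(dose(5, 7780)), 6.43e-7, tolerance = 1e-3)
  expect_identical(dose_to_moles(dose(0, 7780)), 0)
  expect_equal(dose_to_moles(dose(7.78, 7780)), 1e-6)
  expect_error(dose(-5))
})
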