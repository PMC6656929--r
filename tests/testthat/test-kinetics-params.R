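test_that("dissociation rates follow koff = Kd * kon", {
  expect_equal(koff_from_kd(1.85e-9, 5e5), 9.25e-4)
  expect_equal(koff_from_kd(238e-9, 5e5), 0.119)
  expect_identical(koff_from_kd(0, 5e5), 0)
  expect_error(koff_from_kd(-1e-9, 5e5))
  expect_error(koff_from_kd(1e-9, 0))
})

test_that("degradation rates follow ln(2)/half-life", {
  expect_equal(kdeg_from_half_life(300), log(2) / 300)
  expect_equal(kdeg_from_half_life(300), 2.310e-3, tolerance = 1e-3)
  expect_equal(kdeg_from_half_life(3600), 1.925e-4, tolerance = 1e-3)
  expect_equal(kdeg_from_half_life(600), kdeg_from_half_life(300) / 2)
  expect_error(kdeg_from_half_life(0))
})

test_that("cHSPG affinities inherit FGF2 kinetics scaled by relative heparin affinity", {
  ref <- list(kon = 5e5, koff = 0.0195)
  ch <- derive_chspg_rates(fgf2_chspg = ref)
  expect_equal(ch$PF4$koff, ref$koff * 20 / 39)
  expect_equal(ch$V165$koff, ref$koff * 80 / 39)
  expect_equal(ch$FGF2$koff, ref$koff)
  expect_true(all(vapply(ch, function(b) b$kon == ref$kon, logical(1))))
  expect_error(derive_chspg_rates(heparin_kd = c(PF4 = 20e-9), fgf2_chspg = ref),
               "FGF2")
})

test_that("heparin affinity order PF4 > FGF2 > TSP1 > V165 survives derivation", {
  p <- default_parameters()
  ch_koff <- vapply(p$binding[c("p_ch", "f_ch", "t_ch", "v_ch")],
                    function(b) b$koff, numeric(1))
  ih_koff <- vapply(p$binding[c("p_ih", "f_ih", "t_ih", "v_ih")],
                    function(b) b$koff, numeric(1))
  expect_true(all(diff(ch_koff) > 0))
  expect_true(all(diff(ih_koff) > 0))
})

test_that("fold scalings derive the VEGF-axis rates and are single-shot", {
  base <- list(v_n_hspg = list(kon = 3.2e6, koff = 1e-3),
               c_vr2_n_hspg = list(kon = 3.2e6, koff = 1e-3),
               c_n_h = list(kon = 1e7, koff = 1e-3))
  scaled <- apply_fold_scalings(base)
  kd <- function(b) b$koff / b$kon
  expect_equal(kd(scaled$v_n_alone), 20 * kd(scaled$v_n_hspg))
  expect_equal(kd(scaled$c_r1_h), kd(scaled$c_n_h) / 5)
  expect_equal(kd(scaled$c_r1_n), kd(scaled$c_n_h) * 10)
  expect_equal(kd(scaled$c_vn_h), kd(scaled$c_n_h) / 10)
  expect_error(apply_fold_scalings(scaled), "single-shot")
  expect_error(apply_fold_scalings(base[1:2]), "c_n_h")
})

test_that("qualitative expression levels map to the density convention", {
  expect_identical(expression_level_density(c("low", "medium", "high")),
                   c(2500, 5000, 10000))
  expect_error(expression_level_density("enormous"), "unknown")
})

test_that("the shipped parameter file passes validation and covers the model", {
  path <- angionet_files()[["parameters"]]
  expect_true(file.exists(path))
  p <- load_parameters(path)
  d <- p$densities
  expect_identical(d$value[d$species == "CXCR3" & d$side == "ec"], 2500)
  expect_true(all(d$value >= 0))
})

test_that("inconsistent or incomplete parameter files are rejected", {
  p <- default_parameters()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, tmp)
  doc <- yaml::read_yaml(tmp)
  doc$binding$p_cxcr3$Kd <- doc$binding$p_cxcr3$Kd * 1.5
  yaml::write_yaml(doc, tmp)
  expect_error(load_parameters(tmp), "inconsistent Kd")

  doc$binding$p_cxcr3$Kd <- NULL
  doc$production$q_pf4 <- NULL
  yaml::write_yaml(doc, tmp)
  expect_error(load_parameters(tmp), "unresolved rate")
})

test_that("production and density multipliers target the right entries", {
  p <- default_parameters()
  p2 <- scale_parameters(p, production = c(VEGF = 2), densities = c(cHSPG = 10))
  v_names <- c("q_v165_ec", "q_v165_tc", "q_v121_ec", "q_v121_tc")
  expect_equal(unname(p2$production[v_names]), unname(p$production[v_names]) * 2)
  expect_equal(p2$production[["q_pf4"]], p$production[["q_pf4"]])
  hit <- p$densities$species == "cHSPG"
  expect_equal(p2$densities$value[hit], p$densities$value[hit] * 10)
  expect_error(scale_parameters(p, production = c(ALBUMIN = 2)), "unknown")
  expect_error(scale_parameters(p, densities = c(ALBUMIN = 2)), "unknown")
})
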