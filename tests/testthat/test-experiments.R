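test_that("calibration returns unit multipliers when targets equal predictions", {
  # the shipped baseline is the calibrated state, so re-calibrating against
  # the same aims is a fixpoint
  cal <- calibrate_baseline(ang_net(), ang_params(), ang_geom())
  expect_true(cal$converged)
  expect_identical(max(cal$history$pass), 1L)
  expect_equal(unname(cal$multipliers), rep(1, 6))
})

test_that("calibrating to a doubled aim is reproduced by forward simulation", {
  net <- ang_net(); geom <- ang_geom()
  targets <- table1_targets()[3, ]   # unbound PF4, controlled by q_pf4
  targets$aim <- targets$aim * 2
  cal <- calibrate_baseline(net, ang_params(), geom, targets = targets,
                            tol = 0.05)
  expect_true(cal$converged)
  ss <- run_to_steady_state(assemble_odes(net, cal$params, geom))
  got <- fluid_obs(ss$state, observable_weights(net)["PF4_unbound"], geom)
  expect_equal(unname(got), targets$aim, tolerance = 0.05)
})

test_that("secretion scans are normalized to the baseline grid point", {
  sc <- secretion_scan_2d(ang_net(), ang_params(), ang_geom(),
                          factor_pair = c("VEGF", "TSP1"),
                          multipliers = c(0.1, 1, 10))
  expect_identical(nrow(sc), 9L)
  base <- sc[sc$m1 == 1 & sc$m2 == 1, ]
  for (col in c("VEGF_signaling_norm", "FGF2_signaling_norm",
                "TSP1_signaling_norm", "PF4_signaling_norm", "ratio_norm")) {
    expect_equal(base[[col]], 1)
  }
  expect_true(all(sc$converged))
  # VEGF signaling rises monotonically with VEGF secretion at fixed TSP1
  slice <- sc[sc$m2 == 1, ]
  slice <- slice[order(slice$m1), ]
  expect_true(all(diff(slice$VEGF_signaling) > 0))
  expect_error(secretion_scan_2d(ang_net(), ang_params(), ang_geom(),
                                 multipliers = c(0.1, 10)),
               "baseline point")
})

test_that("the log-uniform secretion sampler is reproducible and well-distributed", {
  s1 <- sample_secretion_multipliers(1000, seed = 123)
  s2 <- sample_secretion_multipliers(1000, seed = 123)
  expect_identical(s1, s2)
  expect_error(sample_secretion_multipliers(10), "seed")
  for (f in c("VEGF", "TSP1", "PF4", "FGF2", "MMP3", "proMMP9")) {
    x <- s1[[f]]
    expect_gte(min(x), 0.01)
    expect_lte(max(x), 10)
    ks <- stats::ks.test(log10(x), "punif", -2, 1)
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Monte Carlo secretion sampling preserves the distribution conclusions", {
  mc <- monte_carlo_secretion(ang_net(), ang_params(), ang_geom(),
                              n = 6, seed = 7)
  expect_identical(nrow(mc), 6L)
  expect_true(all(mc$converged))
  # the distribution conclusions hold for the majority of samples:
  # VEGF predominantly surface-bound, PF4 predominantly interstitial
  expect_gt(mean(mc$VEGF_surface_pct > 50), 0.5)
  expect_true(all(mc$PF4_surface_pct < 50))
  mc2 <- monte_carlo_secretion(ang_net(), ang_params(), ang_geom(),
                               n = 6, seed = 7)
  expect_identical(mc$ratio, mc2$ratio)
})

test_that("cHSPG x PF4 grids normalize to the low-PF4 reference per level", {
  gr <- chspg_pf4_grid(ang_net(), ang_params(), ang_geom(),
                       chspg_multipliers = c(0.1, 1, 10),
                       pf4_multipliers = c(0.01, 1, 10))
  expect_true(all(gr$converged))
  ref <- gr[gr$pf4 == 0.01, ]
  expect_equal(ref$VEGF_signaling_fold, rep(1, 3))
  expect_equal(ref$FGF2_dimer_fold, rep(1, 3))
  # FGF2 signaling dimers decrease with PF4 secretion at every cHSPG level
  mono <- gr %>% dplyr::group_by(chspg) %>%
    dplyr::arrange(pf4, .by_group = TRUE) %>%
    dplyr::summarise(dec = all(diff(FGF2_dimer) < 0))
  expect_true(all(mono$dec))
})

test_that("a short pulse protocol tracks the depot and recovers afterwards", {
  pr <- pf4_pulse(ang_net(), ang_params(), ang_geom(), chspg_level = 1,
                  d = dose(mass_mg = 1), pulse_days = 0.5, duration_days = 1.5)
  expect_s3_class(pr, "angio_pulse")
  expect_gt(pr$peak_pf4_nM, 10)   # far above the ~5 nM baseline
  pf4 <- pr$trajectory %>% dplyr::filter(observable == "PF4_unbound")
  expect_lt(pf4$conc_pM[[1L]] / 1000, 10)
  peak_t <- pf4$time_days[which.max(pf4$conc_pM)]
  expect_gt(peak_t, 0.5)          # the peak follows the release onset
  fc <- pr$fold_changes
  expect_identical(fc$direction[fc$observable == "FGF2_dimer"], "decrease")
})

test_that("the analytic quasi-steady pulse peak matches its closed form", {
  expect_equal(pulse_peak_analytic(dose(5, 7780, 2.8e-5),
                                   kdeg_from_half_life(300), geometry()),
               (5e-3 / 7780) * 2.8e-5 /
                 (log(2) / 300 * 33 * 0.31 / 1000))
})
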