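test_that("every factor's distribution closes to 100 percent", {
  prof <- distribution_profile(ang_baseline_ss())
  sums <- prof %>% dplyr::group_by(factor) %>%
    dplyr::summarise(s = sum(percent))
  expect_equal(sums$s, rep(100, 4), tolerance = 1e-6)
  expect_setequal(unique(prof$factor), c("VEGF", "FGF2", "TSP1", "PF4"))
})

test_that("every factor-containing species maps to exactly one category per factor", {
  mem <- attr(distribution_profile(ang_baseline_ss()), "membership")
  dup <- mem %>% dplyr::count(.data$index, .data$factor) %>% dplyr::filter(n > 1)
  expect_identical(nrow(dup), 0L)
  # complexes holding two tracked factors count toward both factor-bound pools
  fb <- mem[mem$category == "interstitial:factor_bound", ]
  per_species <- fb %>% dplyr::count(.data$index)
  expect_true(all(per_species$n >= 2L))
  expect_true(any(grepl("^TSP1", fb$id) & grepl("V165", fb$id)))
})

test_that("a state with only free ligand is 100 percent interstitial unbound", {
  net <- ang_net()
  state <- stats::setNames(numeric(length(net$ids)), net$ids)
  state[["V165@interstitium"]] <- 1e-13
  state[["V121@interstitium"]] <- 1e-13
  prof <- distribution_profile(state, net)
  vegf <- prof[prof$factor == "VEGF", ]
  expect_equal(vegf$percent[vegf$category == "interstitial:unbound"], 100)
})

test_that("the angiogenic ratio decomposes exactly into its listed components", {
  ss <- ang_baseline_ss()
  rat <- angiogenic_ratio(ss)
  comp <- attr(rat, "components")
  expect_identical(sum(comp$conc[comp$side == "pro"]), rat$numerator)
  expect_identical(sum(comp$conc[comp$side == "anti"]), rat$denominator)
  expect_true(rat$finite)
  expect_gt(rat$ratio, 0)
})

test_that("a hand-built state reproduces ratio arithmetic and the zero-denominator flag", {
  net <- ang_net()
  sig <- angionet:::signaling_membership(net)
  state <- stats::setNames(numeric(length(net$ids)), net$ids)
  state[[sig$VEGF[[1L]]]] <- 3.4e-9
  state[[sig$PF4[[1L]]]] <- 2.0e-9
  expect_equal(angiogenic_ratio(state, net)$ratio, 1.7)
  state[[sig$PF4[[1L]]]] <- 0
  rat <- angiogenic_ratio(state, net)
  expect_false(rat$finite)
  expect_identical(rat$ratio, Inf)
})

test_that("signaling membership matches the pathway definitions", {
  net <- ang_net()
  sig <- angionet:::signaling_membership(net)
  # dimerized FGF2 complexes are the only FGF2 signaling form
  expect_true(all(vapply(sig$FGF2, function(i) {
    sum(net$species[[i]]$types == "FGFR1") >= 2L
  }, logical(1))))
  # cHSPG-only VEGF complexes are never signaling
  vh <- which(net$ids == "V165(n!1).cHSPG(hs!1)@endothelial_surface")
  expect_false(vh %in% sig$VEGF)
  # NRP1-bound VEGF counts as signaling
  expect_true(any(vapply(sig$VEGF, function(i) {
    "NRP1" %in% net$species[[i]]$types
  }, logical(1))))
})
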