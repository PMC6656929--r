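mk_tiny_params <- function(binding = list(), half_life = c(), production = c(),
                           uni = c(), densities = NULL) {
  if (is.null(densities)) {
    densities <- tibble::tibble(species = character(), side = character(),
                                value = numeric(), units = character(),
                                provenance = character())
  }
  structure(list(binding = binding, unimolecular = uni, catalytic = c(),
                 half_life = half_life, production = production,
                 densities = densities),
            class = "angio_params")
}

decay_spec <- function() {
  M <- stats::setNames(list(monomer("X", character(), "soluble")), "X")
  seeds <- list(list(complex = complex_new("X", list(), "interstitium", M),
                     init = "zero"))
  deg <- rule("deg.X", "degradation", list(pattern("X", comp = "interstitium")),
              rate_fwd = "kdeg_x")
  model_spec(M, seeds, list(deg), name = "decay")
}

test_that("the assembled right-hand side has the textbook mass-action form", {
  fx <- generate_fixture("ligand_receptor", kd = 10e-9)
  net <- expand_network(fx$spec)
  geom <- geometry()
  sys <- assemble_odes(net, fx$params, geom)
  iL <- match("L@interstitium", net$ids)
  iR <- match("R@endothelial_surface", net$ids)
  iC <- setdiff(1:3, c(iL, iR))
  x <- numeric(3); x[iL] <- 2e-13; x[iR] <- 3e-13; x[iC] <- 1e-13
  d <- angionet:::ode_rhs(sys)(0, x, NULL)[[1L]]
  kon_t <- 5e5 * 1000 / geom$interstitial_fluid_fraction
  koff <- 5e5 * 10e-9
  expect_equal(d[iC], kon_t * x[iL] * x[iR] - koff * x[iC])
  expect_equal(d[iL], -d[iC])
  expect_equal(d[iR], -d[iC])
})

test_that("the builtin system has one state per species and a quiescent zero state", {
  net <- ang_net()
  p <- ang_params()
  p$production[] <- 0
  sys <- assemble_odes(net, p, ang_geom())
  expect_identical(sys$n, length(net$ids))
  d <- angionet:::ode_rhs(sys)(0, numeric(sys$n), NULL)[[1L]]
  expect_identical(max(abs(d)), 0)
})

test_that("pure first-order decay matches the closed form", {
  spec <- decay_spec()
  net <- expand_network(spec)
  sys <- assemble_odes(net, mk_tiny_params(half_life = c(X = 300)), geometry())
  x0 <- 1e-12
  traj <- integrate_network(sys, times = c(0, 300, 600), x0 = x0)
  expect_equal(unname(traj$state[2, 1]) / x0, 0.5, tolerance = 1e-5)
  expect_equal(unname(traj$state[3, 1]) / x0, 0.25, tolerance = 1e-5)
})

test_that("depot release follows 1 - exp(-k t) when there are no sinks", {
  fx <- generate_fixture("depot_decay")
  net <- expand_network(fx$spec)
  geom <- geometry()
  sys <- assemble_odes(net, fx$params, geom)
  amount <- 1e-6
  k_rel <- fx$oracle$k_rel
  traj <- integrate_network(sys, times = seq(0, 2e5, by = 2e4),
                            depots = list(list(target = "D@interstitium",
                                               k_rel = k_rel,
                                               doses = data.frame(time = 0,
                                                                  amount_mol = amount))))
  released <- traj$state[, "D@interstitium"] * geom$tumor_volume_cm3 / amount
  expect_equal(released, fx$oracle$released_fraction(traj$times), tolerance = 1e-6)
})

test_that("reversible binding reaches the quadratic closed-form equilibrium", {
  fx <- generate_fixture("ligand_receptor", kd = 10e-9,
                         totals = c(L = 1e-9, R = 1e-9))
  net <- expand_network(fx$spec)
  geom <- geometry()
  sys <- assemble_odes(net, fx$params, geom)
  x0 <- sys$x0
  x0[match("L@interstitium", net$ids)] <- fluid_to_tissue_concentration(1e-9, geom)
  ss <- run_to_steady_state(sys, x0 = x0)
  iC <- match("L(b!1).R(b!1)@endothelial_surface", net$ids)
  got <- tissue_to_fluid_concentration(ss$state[[iC]], geom, "M")
  expect_equal(got, fx$oracle$equilibrium_M[["C"]], tolerance = 1e-6)
})

test_that("two-receptor competition matches the root-found oracle", {
  fx <- generate_fixture("competition", kd = c(1e-9, 50e-9),
                         totals = c(L = 2e-9, R1 = 1e-9, R2 = 3e-9))
  net <- expand_network(fx$spec)
  expect_identical(length(net$ids), fx$oracle$n_species)
  expect_identical(nrow(net$reactions), fx$oracle$n_reactions)
  geom <- geometry()
  sys <- assemble_odes(net, fx$params, geom)
  x0 <- sys$x0
  x0[match("L@interstitium", net$ids)] <- fluid_to_tissue_concentration(2e-9, geom)
  ss <- run_to_steady_state(sys, x0 = x0)
  got_L <- tissue_to_fluid_concentration(ss$state[["L@interstitium"]], geom, "M")
  expect_equal(got_L, fx$oracle$equilibrium_M[["L"]], tolerance = 1e-4)
})

test_that("production/degradation balance gives C* = q_total/(kdeg * V_fluid)", {
  M <- stats::setNames(list(monomer("X", character(), "soluble")), "X")
  seeds <- list(list(complex = complex_new("X", list(), "interstitium", M),
                     init = "zero"))
  rules <- list(
    rule("q.X", "production", list(), rate_fwd = "q_x",
         products = list(complex_new("X", list(), "interstitium", M))),
    rule("deg.X", "degradation", list(pattern("X", comp = "interstitium")),
         rate_fwd = "kdeg_x"))
  spec <- model_spec(M, seeds, rules)
  geom <- geometry()
  q <- 3e9  # molecules/cm^3/s
  sys <- assemble_odes(expand_network(spec),
                       mk_tiny_params(half_life = c(X = 300),
                                      production = c(q_x = q)), geom)
  ss <- run_to_steady_state(sys)
  expect_true(ss$converged)
  q_total_mol_s <- q * geom$tumor_volume_cm3 / angionet:::AVOGADRO
  expected_M <- q_total_mol_s / (kdeg_from_half_life(300) *
                                   interstitial_fluid_volume(geom))
  got_M <- tissue_to_fluid_concentration(ss$state[[1L]], geom, "M")
  expect_equal(got_M, expected_M, tolerance = 1e-4)
})

test_that("the baseline steady state is independent of the initial condition", {
  # receptor and HSPG totals are conserved quantities, so the comparison
  # initial state may only perturb the soluble pools: double every species
  # that contains no surface- or matrix-fixed monomer
  ss1 <- ang_baseline_ss()
  sys <- ss1$sys
  net <- ang_net()
  soluble <- vapply(net$species, function(cpx) {
    all(vapply(cpx$types, function(tp) {
      net$spec$monomers[[tp]]$mobility == "soluble"
    }, logical(1)))
  }, logical(1))
  x2 <- unname(ss1$state)
  x2[soluble] <- 2 * x2[soluble]
  ss2 <- run_to_steady_state(sys, x0 = x2)
  keep <- ss1$state > max(ss1$state) * 1e-6
  expect_lt(max(abs(ss2$state[keep] - ss1$state[keep]) / ss1$state[keep]), 1e-3)
})

test_that("steady state with the shipped parameters is reached within the first day", {
  ss <- ang_baseline_ss()
  expect_true(ss$converged)
  expect_lte(ss$time, 86400)
})

test_that("receptor and HSPG totals are conserved along the baseline trajectory", {
  sys <- ang_baseline_ss()$sys
  traj <- integrate_network(sys, seq(0, 86400, by = 7200))
  expect_true(all(traj$state >= 0))
  rep <- conservation_report(traj, ang_net())
  expect_identical(nrow(rep), 21L)  # 10 surface pools x 2 surfaces + iHSPG
  expect_lt(max(rep$max_rel_drift), 1e-6)
  expect_lt(rep$max_rel_drift[rep$pool == "iHSPG@interstitium"], 1e-9)
})

test_that("broken receptor recycling is detected as conservation drift", {
  spec <- toy_model()
  eat <- rule("eat.C", "degradation",
              list(pattern(c("L", "R"), bonds = list(c(1, "b", 2, "b")),
                           comp = "surface")),
              rate_fwd = "kdeg_c")
  spec2 <- model_spec(spec$monomers, spec$seeds, c(spec$rules, list(eat)),
                      name = "leaky")
  net <- expand_network(spec2)
  geom <- geometry()
  params <- toy_params()
  params$half_life <- c(C = 1800)
  names(params$half_life) <- "c"
  sys <- assemble_odes(net, params, geom)
  x0 <- sys$x0
  x0[match("L@interstitium", net$ids)] <- fluid_to_tissue_concentration(1e-9, geom)
  traj <- integrate_network(sys, seq(0, 7200, by = 1800), x0 = x0)
  rep <- conservation_report(traj, net)
  expect_gt(rep$max_rel_drift[rep$pool == "R@endothelial_surface"], 1e-3)
})

test_that("every isolated reversible pair in the network equilibrates to its Kd", {
  net <- ang_net()
  pairs <- angionet:::binding_pair_table(net)
  pairs <- pairs[!duplicated(paste(pairs$kon, pairs$koff)), ]
  expect_gt(nrow(pairs), 20L)
  rates <- param_rates(ang_params())
  lookup <- stats::setNames(rates$value, rates$name)
  geom <- ang_geom()
  f <- geom$interstitial_fluid_fraction
  for (j in seq_len(nrow(pairs))) {
    kon <- lookup[[pairs$kon[[j]]]]
    koff <- lookup[[pairs$koff[[j]]]]
    kd <- koff / kon
    A0 <- 2 * kd; B0 <- 0.5 * kd   # molar totals around Kd
    kon_t <- kon * 1000 / f
    a0 <- A0 * f / 1000; b0 <- B0 * f / 1000
    rhs <- function(t, y, p) {
      v <- kon_t * y[1] * y[2] - koff * y[3]
      list(c(-v, -v, v))
    }
    out <- deSolve::lsoda(c(a0, b0, 0), c(0, 200 / koff), rhs, NULL,
                          rtol = 1e-10, atol = 1e-25)
    yf <- out[nrow(out), -1]
    kd_sim <- (yf[1] * yf[2] / yf[3]) * 1000 / f
    expect_equal(unname(kd_sim), kd, tolerance = 1e-3)
  }
})

test_that("non-convergence within the cap is flagged, not silent", {
  M <- stats::setNames(list(monomer("X", character(), "soluble")), "X")
  seeds <- list(list(complex = complex_new("X", list(), "interstitium", M),
                     init = "zero"))
  grow <- rule("q.X", "production", list(), rate_fwd = "q_x",
               products = list(complex_new("X", list(), "interstitium", M)))
  sys <- assemble_odes(expand_network(model_spec(M, seeds, list(grow))),
                       mk_tiny_params(production = c(q_x = 1e9)), geometry())
  expect_warning(ss <- run_to_steady_state(sys, max_time = 7200), "hard cap")
  expect_false(ss$converged)
})
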