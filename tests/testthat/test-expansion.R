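test_that("the toy network expands to the hand-enumerated species and reactions", {
  net <- expand_network(toy_model())
  expect_identical(length(net$ids), 3L)
  expect_identical(nrow(net$reactions), 2L)
  rt <- reaction_table(net)
  fw <- rt[!is.na(rt$reactant2), ]
  expect_identical(fw$rate, "kon_lr")
  expect_identical(sort(c(fw$reactant1, fw$reactant2)),
                   sort(c("L@interstitium", "R@endothelial_surface")))
})

test_that("a ruleless model expands to its seeds only", {
  M <- list(monomer("A", character(), "soluble"),
            monomer("B", character(), "soluble"))
  names(M) <- c("A", "B")
  seeds <- list(list(complex = complex_new("A", list(), "interstitium", M), init = "zero"),
                list(complex = complex_new("B", list(), "interstitium", M), init = "zero"))
  net <- expand_network(model_spec(M, seeds, list()))
  expect_identical(length(net$ids), 2L)
  expect_identical(nrow(net$reactions), 0L)
})

test_that("expansion is a fixpoint: re-expanding from all species adds nothing", {
  net <- ang_net()
  spec <- builtin_model()
  seeds2 <- lapply(seq_along(net$ids), function(i) {
    list(complex = net$species[[i]], init = net$init[[i]])
  })
  net2 <- expand_network(model_spec(spec$monomers, seeds2, spec$rules,
                                    name = "refixed"))
  expect_identical(net2$ids, net$ids)
  expect_identical(nrow(net2$reactions), nrow(net$reactions))
  k1 <- with(net$reactions, paste(rule, reactant1, reactant2,
                                  vapply(products, paste, "", collapse = ","), rate, mult))
  k2 <- with(net2$reactions, paste(rule, reactant1, reactant2,
                                   vapply(products, paste, "", collapse = ","), rate, mult))
  expect_setequal(k1, k2)
})

test_that("shuffling seed and rule order yields an identical canonical network", {
  spec <- builtin_model()
  net <- ang_net()
  withr::with_seed(7, {
    spec2 <- model_spec(spec$monomers,
                        spec$seeds[sample(length(spec$seeds))],
                        spec$rules[sample(length(spec$rules))],
                        name = spec$name)
  })
  net2 <- expand_network(spec2)
  expect_identical(net2$ids, net$ids)
  ord <- function(rx) rx[order(rx$rule, rx$reactant1, rx$reactant2, rx$rate), ]
  expect_identical(ord(reaction_table(net2)), ord(reaction_table(net)))
})

test_that("complex size stays bounded in the builtin expansion", {
  sizes <- vapply(ang_net()$species, angionet:::cpx_size, integer(1))
  expect_lte(max(sizes), 8L)
})

test_that("runaway polymerization rules hit the species cap with a clear error", {
  M <- list(monomer("A", c("head", "tail"), "soluble"))
  names(M) <- "A"
  seeds <- list(list(complex = complex_new("A", list(), "interstitium", M),
                     init = "zero"))
  chain <- rule("A.chain", "binding",
                list(P1("A", head = "free"), P1("A", tail = "free")),
                rate_fwd = "kon_a", rate_rev = "koff_a",
                bond = list(c(1L, "head"), c(1L, "tail")))
  expect_error(expand_network(model_spec(M, seeds, list(chain)), max_species = 20L),
               "unbounded polymerization")
})

test_that("network summary counts species per compartment", {
  s <- network_summary(ang_net())
  expect_identical(s$counts$n_species, length(ang_net()$ids))
  expect_identical(s$counts$n_endothelial_surface, s$counts$n_tumor_surface)
  expect_gt(s$counts$n_interstitium, 0L)
  empty <- expand_network(model_spec(
    stats::setNames(list(monomer("A", character(), "soluble")), "A"),
    list(list(complex = complex_new("A", list(), "interstitium",
                                    stats::setNames(list(monomer("A", character(), "soluble")), "A")),
              init = "zero")),
    list()))
  expect_identical(network_summary(empty)$counts$n_reactions, 0L)
})

test_that("explicit-table mode reproduces the rule-expanded right-hand side", {
  net <- ang_net()
  net2 <- network_from_tables(species_table(net), reaction_table(net))
  geom <- ang_geom()
  sys1 <- assemble_odes(net, ang_params(), geom)
  sys2 <- assemble_odes(net2, ang_params(), geom)
  rhs1 <- angionet:::ode_rhs(sys1)
  rhs2 <- angionet:::ode_rhs(sys2)
  withr::with_seed(11, {
    for (k in 1:100) {
      x <- stats::runif(sys1$n) * 1e-12
      d1 <- rhs1(0, x, NULL)[[1L]]
      d2 <- rhs2(0, x, NULL)[[1L]]
      expect_lt(max(abs(d1 - d2)) / max(abs(d1)), 1e-10)
    }
  })
})
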