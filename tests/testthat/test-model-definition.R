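test_that("the builtin model validates and reports stable structural counts", {
  spec <- builtin_model()
  rep <- validate_spec(spec)
  expect_true(attr(rep, "valid"))
  s <- model_summary(spec)
  expect_identical(s$n_monomers, 21L)
  expect_gt(s$n_seeds, 0L)
  expect_gt(s$n_rules, 0L)
  # deterministic: two independent constructions are identical
  expect_identical(builtin_model(), builtin_model())
})

test_that("removing one signaling axis drops exactly its rules and still validates", {
  spec <- builtin_model()
  fgf2_rules <- vapply(spec$rules, function(r) grepl("panel D", r$notes), logical(1))
  expect_identical(sum(fgf2_rules), 5L)
  trimmed <- model_spec(spec$monomers, spec$seeds, spec$rules[!fgf2_rules],
                        name = "no_fgf2_axis")
  expect_identical(length(trimmed$rules), length(spec$rules) - 5L)
  expect_true(attr(validate_spec(trimmed), "valid"))
})

test_that("the toy fixture has two seeds and one rule", {
  s <- model_summary(toy_model())
  expect_identical(s$n_seeds, 2L)
  expect_identical(s$n_rules, 1L)
})

test_that("structural violations are reported per invariant", {
  M <- builtin_monomers()
  three_pat <- rule("bad3", "binding",
                    list(P1("V165"), P1("V121"), P1("FGF2")),
                    rate_fwd = "k", bond = list(c(1L, "r"), c(1L, "r")))
  spec <- model_spec(M, builtin_seeds(M), list(three_pat))
  rep <- validate_spec(spec)
  expect_false(rep$ok[rep$check == "max_two_reactant_patterns"])

  prod_bad <- rule("badprod", "production", list(P1("V165")),
                   rate_fwd = "q_x",
                   products = list(complex_new("V165", list(), "interstitium", M)))
  rep <- validate_spec(model_spec(M, builtin_seeds(M), list(prod_bad)))
  expect_false(rep$ok[rep$check == "production_rules_have_no_reactants"])

  ghost <- rule("ghost", "binding",
                list(P1("V165", q = "free"), P1("VEGFR2")),
                rate_fwd = "kon_x", rate_rev = "koff_x",
                bond = list(c(1L, "q"), c(1L, "l")))
  rep <- validate_spec(model_spec(M, builtin_seeds(M), list(ghost)))
  bad <- rep[rep$check == "monomers_and_sites_declared", ]
  expect_false(bad$ok)
  expect_match(bad$detail, "ghost")   # offending rule is named
})

test_that("unknown rule classes and monomers are rejected at construction", {
  expect_error(rule("x", "teleportation", list(), rate_fwd = "k"), "rule_class")
  expect_error(monomer("X", c("a", "a")), "duplicate site")
  expect_error(monomer("X", "a", "floaty"), "mobility")
})
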