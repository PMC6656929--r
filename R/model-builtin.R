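# The transcribed extracellular angiogenic network: VEGF (V165/V121/V114),
# FGF2, TSP1 (+ cleaved TSP1c), PF4, their receptors on the endothelial and
# tumor cell surfaces, the two heparan sulfate proteoglycan pools (cHSPG on
# each surface, iHSPG in the interstitium) and the MMP proteolysis chain.
#
# Surface rules are written with a compartment-wildcard ("surface"), so one
# rule covers both cell surfaces with identical kinetics; the two surfaces
# differ only in receptor/cHSPG densities. A rule <-> schematic-panel mapping
# table ships with the package (builtin_rule_map()).

#' Monomer inventory of the builtin angiogenic network
#' @return Named list of [monomer()] declarations.
#' @export
builtin_monomers <- function() {
  ms <- list(
    # soluble factors; site r = receptor-binding, n = exon-7 (NRP1/HSPG),
    # h = heparin-binding, hs = heparan sulfate, f = factor-factor
    monomer("V165", c("r", "n"), "soluble"),
    monomer("V121", c("r"), "soluble"),
    monomer("V114", character(), "soluble"),      # cleaved, inert
    monomer("FGF2", c("r", "h"), "soluble"),
    monomer("TSP1", c("hs", "r", "f"), "soluble"),
    monomer("TSP1c", character(), "soluble"),     # cleaved, inert
    monomer("PF4", c("hs", "r", "f"), "soluble"),
    monomer("MMP3", character(), "soluble"),
    monomer("proMMP9", character(), "soluble"),
    monomer("MMP9", c("r"), "soluble"),           # r binds LRP1 (clearance)
    # receptors; l = ligand, c = lateral coupling, d = dimerization
    monomer("VEGFR1", c("l", "c"), "surface_fixed"),
    monomer("VEGFR2", c("l", "c"), "surface_fixed"),
    monomer("NRP1", c("v", "r", "h"), "surface_fixed"),
    monomer("FGFR1", c("l", "d"), "surface_fixed"),
    monomer("CD36", c("l", "c"), "surface_fixed"),
    monomer("CD47", c("l", "c"), "surface_fixed"),
    monomer("LRP1", c("l", "c"), "surface_fixed"),
    monomer("B1", c("l", "c"), "surface_fixed"),  # alpha-x beta-1 integrins
    monomer("CXCR3", c("l"), "surface_fixed"),
    monomer("cHSPG", c("hs"), "surface_fixed"),
    monomer("iHSPG", c("hs"), "matrix_fixed")
  )
  names(ms) <- vapply(ms, function(m) m$name, character(1))
  ms
}

free_species <- function(type, comp, monomers) {
  list(complex = complex_new(type, list(), comp, monomers))
}

#' Seed species of the builtin network
#' @param monomers Named list of monomer declarations.
#' @return List of seed species records (complex + init reference).
#' @export
builtin_seeds <- function(monomers = builtin_monomers()) {
  surf_types <- c("VEGFR1", "VEGFR2", "NRP1", "FGFR1", "CD36", "CD47",
                  "LRP1", "B1", "CXCR3", "cHSPG")
  sol_types <- c("V165", "V121", "V114", "FGF2", "TSP1", "TSP1c", "PF4",
                 "MMP3", "proMMP9", "MMP9")
  seeds <- list()
  for (comp in surface_tags()) {
    side <- if (comp == "endothelial_surface") "ec" else "tc"
    for (t in surf_types) {
      s <- free_species(t, comp, monomers)
      s$init <- paste0("density:", t, ":", side)
      seeds[[length(seeds) + 1L]] <- s
    }
  }
  for (t in sol_types) {
    s <- free_species(t, "interstitium", monomers)
    s$init <- "zero"
    seeds[[length(seeds) + 1L]] <- s
  }
  s <- free_species("iHSPG", "interstitium", monomers)
  s$init <- "density:iHSPG:matrix"
  seeds[[length(seeds) + 1L]] <- s
  seeds
}

# binding-rule shorthand: join site s1 of pattern p1 with site s2 of p2
bind_rule <- function(id, p1, s1, p2, s2, kon, koff, notes = "",
                      class = "binding", i1 = 1L, i2 = 1L) {
  # the joined sites must be free in the patterns
  c1 <- p1$cond[[i1]]; c1[[s1]] <- "free"; p1$cond[[i1]] <- c1
  c2 <- p2$cond[[i2]]; c2[[s2]] <- "free"; p2$cond[[i2]] <- c2
  rule(id, class, list(p1, p2), rate_fwd = kon, rate_rev = koff,
       bond = list(c(i1, s1), c(i2, s2)), notes = notes)
}

deg_rule <- function(id, type, rate, monomers, notes = "degradation of free soluble species") {
  rule(id, "degradation",
       list(pattern(type, comp = "interstitium")),
       rate_fwd = rate, notes = notes)
}

prod_rule <- function(id, type, rate, monomers, notes = "") {
  rule(id, "production", list(), rate_fwd = rate,
       products = list(complex_new(type, list(), "interstitium", monomers)),
       notes = notes)
}

int_rule <- function(id, type, site, cond, notes = "") {
  cnd <- stats::setNames(list(cond), site)
  rule(id, "internalization",
       list(pattern(type, cond = list(unlist(cnd)), comp = "surface")),
       rate_fwd = "kint", notes = notes)
}

#' The builtin tumor-tissue angiogenic network
#'
#' Returns the transcribed model: monomer inventory, seed species on both cell
#' surfaces and in the interstitium, and the full reaction-rule catalogue for
#' the VEGF, TSP1, FGF2 and PF4 axes, the interstitial factor-factor and
#' iHSPG interactions, the MMP proteolysis chain, and production,
#' degradation and internalization processes.
#'
#' Key structural constraints encoded here: VEGF165 does not bind VEGFR1
#' pre-coupled with NRP1; cHSPG affects VEGFR2 only through V165 bridging;
#' V165's exon-7 site is shared between NRP1 and HSPG (ternary
#' VEGFR2-V165-NRP1:cHSPG complexes arise via NRP1 pre-coupled to cHSPG);
#' FGF2 signaling complexes assemble HSPG-first (FGF2 + cHSPG -> + FGFR1 ->
#' trimer -> dimer); cleaved V114 and TSP1c are inert and only degrade.
#'
#' @param validate Run [assert_valid_spec()] before returning (default TRUE).
#' @return An `angio_model`.
#' @export
builtin_model <- function(validate = TRUE) {
  M <- builtin_monomers()
  r <- list()
  add <- function(x) r[[length(r) + 1L]] <<- x

  ## --- VEGF axis (cell surfaces) -------------------------------------------
  # V165 <-> VEGFR2 (solution binding; n site free)
  add(bind_rule("V.R2", P1("V165", n = "free", comp = "interstitium"), "r",
                P1("VEGFR2", comp = "surface"), "l",
                "kon_v165_r2", "koff_v165_r2", "panel A: V165+VEGFR2"))
  # cHSPG-bound V165 couples VEGFR2 (V165-mediated VEGFR2-HSPG interaction)
  add(bind_rule("VH.R2", P1("V165", n = "cHSPG:hs", comp = "surface"), "r",
                P1("VEGFR2", comp = "surface"), "l",
                "kon_c_r2_vh", "koff_c_r2_vh", "panel A: VEGFR2 coupling to cHSPG-bound V165",
                class = "coupling"))
  # NRP1-bound V165 couples VEGFR2 (bridging; NRP1 with or without cHSPG)
  add(bind_rule("VN.R2", P1("V165", n = "NRP1:v", comp = "surface"), "r",
                P1("VEGFR2", comp = "surface"), "l",
                "kon_c_r2_vn", "koff_c_r2_vn", "panel A: VEGFR2 coupling to NRP1-bound V165",
                class = "coupling"))
  # V165 <-> NRP1 (alone: 20-fold weaker than NRP1:cHSPG)
  add(bind_rule("V.N", P1("V165", r = "free", comp = "interstitium"), "n",
                P1("NRP1", h = "free", r = "free", comp = "surface"), "v",
                "kon_v_n_alone", "koff_v_n_alone", "panel A: V165+NRP1 (no cHSPG; 20x weaker)"))
  add(bind_rule("V.NH", P1("V165", r = "free", comp = "interstitium"), "n",
                P1("NRP1", h = "cHSPG:hs", r = "free", comp = "surface"), "v",
                "kon_v_n_hspg", "koff_v_n_hspg", "panel A: V165+NRP1:cHSPG"))
  # VEGFR2-bound V165 couples NRP1 / NRP1:cHSPG
  add(bind_rule("VR2.N", P1("V165", r = "VEGFR2:l", comp = "surface"), "n",
                P1("NRP1", h = "free", r = "free", comp = "surface"), "v",
                "kon_c_vr2_n_alone", "koff_c_vr2_n_alone", "panel A: V165:VEGFR2 coupling to NRP1",
                class = "coupling"))
  add(bind_rule("VR2.NH", P1("V165", r = "VEGFR2:l", comp = "surface"), "n",
                P1("NRP1", h = "cHSPG:hs", r = "free", comp = "surface"), "v",
                "kon_c_vr2_n_hspg", "koff_c_vr2_n_hspg", "panel A: V165:VEGFR2 coupling to NRP1:cHSPG",
                class = "coupling"))
  # V165 <-> cHSPG directly (heparin-affinity scaled)
  add(bind_rule("V.cH", P1("V165", r = "free", comp = "interstitium"), "n",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_v_ch", "koff_v_ch", "panel A: V165+cHSPG"))
  add(bind_rule("VR2.cH", P1("V165", r = "VEGFR2:l", comp = "surface"), "n",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_c_vr2_h", "koff_c_vr2_h", "panel A: V165:VEGFR2 coupling to cHSPG",
                class = "coupling"))
  # NRP1 <-> cHSPG coupling (10x stronger when V165 is bound to NRP1)
  add(bind_rule("N.cH", P1("NRP1", v = "free", comp = "surface"), "h",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_c_n_h", "koff_c_n_h", "panel A: NRP1 pre-coupling with cHSPG",
                class = "coupling"))
  add(bind_rule("VN.cH", P1("NRP1", v = "V165:n", comp = "surface"), "h",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_c_vn_h", "koff_c_vn_h", "panel A: V165-synergistic NRP1-cHSPG coupling",
                class = "coupling"))
  # VEGFR1 <-> NRP1 coupling (10x weaker than VEGFR2-NRP1; V165-ligated
  # VEGFR1 excluded, V121-ligated allowed)
  add(bind_rule("R1.N", P1("VEGFR1", l = "free", comp = "surface"), "c",
                P1("NRP1", v = "free", comp = "surface"), "r",
                "kon_c_r1_n", "koff_c_r1_n", "panel A: VEGFR1-NRP1 coupling",
                class = "coupling"))
  add(bind_rule("R1v121.N", P1("VEGFR1", l = "V121:r", comp = "surface"), "c",
                P1("NRP1", v = "free", comp = "surface"), "r",
                "kon_c_r1_n", "koff_c_r1_n", "panel A: V121:VEGFR1-NRP1 coupling",
                class = "coupling"))
  # VEGFR1 <-> cHSPG coupling (5x stronger than NRP1-cHSPG)
  add(bind_rule("R1.cH", P1("VEGFR1", comp = "surface"), "c",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_c_r1_h", "koff_c_r1_h", "panel A: VEGFR1-cHSPG coupling",
                class = "coupling"))
  # V165 <-> VEGFR1 (not pre-coupled with NRP1; cHSPG coupling has no effect)
  add(bind_rule("V.R1", P1("V165", n = "free", comp = "interstitium"), "r",
                P1("VEGFR1", c = "free", comp = "surface"), "l",
                "kon_v165_r1", "koff_v165_r1", "panel A: V165+VEGFR1"))
  add(bind_rule("V.R1H", P1("V165", n = "free", comp = "interstitium"), "r",
                P1("VEGFR1", c = "cHSPG:hs", comp = "surface"), "l",
                "kon_v165_r1", "koff_v165_r1", "panel A: V165+VEGFR1:cHSPG (rate unchanged)"))
  # V121 binds both receptors; coupling state irrelevant
  add(bind_rule("V121.R1", P1("V121", comp = "interstitium"), "r",
                P1("VEGFR1", comp = "surface"), "l",
                "kon_v121_r1", "koff_v121_r1", "panel A: V121+VEGFR1"))
  add(bind_rule("V121.R2", P1("V121", comp = "interstitium"), "r",
                P1("VEGFR2", comp = "surface"), "l",
                "kon_v121_r2", "koff_v121_r2", "panel A: V121+VEGFR2"))

  ## --- TSP1 axis ------------------------------------------------------------
  for (rec in c("CD36", "CD47", "LRP1", "B1")) {
    add(bind_rule(paste0("T.", rec),
                  P1("TSP1", hs = "free", f = "free", comp = "interstitium"), "r",
                  P1(rec, comp = "surface"), "l",
                  paste0("kon_t_", tolower(rec)), paste0("koff_t_", tolower(rec)),
                  paste0("panel B: TSP1+", rec)))
  }
  add(bind_rule("T.cH", P1("TSP1", r = "free", f = "free", comp = "interstitium"), "hs",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_t_ch", "koff_t_ch", "panel B: TSP1+cHSPG"))
  # ligated TSP1 receptors couple VEGFR2 (panel C)
  for (rec in c("CD36", "CD47", "LRP1", "B1")) {
    add(bind_rule(paste0("T", rec, ".R2"),
                  P1(rec, l = "TSP1:r", comp = "surface"), "c",
                  P1("VEGFR2", comp = "surface"), "c",
                  "kon_c_tr_r2", "koff_c_tr_r2",
                  paste0("panel C: TSP1:", rec, " coupling to VEGFR2"),
                  class = "coupling"))
  }

  ## --- FGF2 axis (HSPG-first assembly, panel D) -----------------------------
  add(bind_rule("F.cH", P1("FGF2", r = "free", comp = "interstitium"), "h",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_f_ch", "koff_f_ch", "panel D: FGF2+cHSPG"))
  add(bind_rule("FH.R", P1("FGF2", h = "cHSPG:hs", comp = "surface"), "r",
                P1("FGFR1", d = "free", comp = "surface"), "l",
                "kon_fh_r", "koff_fh_r", "panel D: FGF2:cHSPG+FGFR1 (trimer)",
                class = "coupling"))
  add(bind_rule("F.R", P1("FGF2", h = "free", comp = "interstitium"), "r",
                P1("FGFR1", d = "free", comp = "surface"), "l",
                "kon_f_r", "koff_f_r", "panel D: FGF2+FGFR1 monomer (non-signaling)"))
  # trimer dimerization (signaling complex); symmetric rule, rate k [T]^2
  trimer_pat <- pattern(c("FGFR1", "FGF2", "cHSPG"),
                        cond = list(c(d = "free"), NULL, NULL),
                        bonds = list(c(1, "l", 2, "r"), c(2, "h", 3, "hs")),
                        comp = "surface")
  add(rule("TRI.TRI", "coupling", list(trimer_pat, trimer_pat),
           rate_fwd = "kon_c_dim", rate_rev = "koff_c_dim",
           bond = list(c(1L, "d"), c(1L, "d")),
           notes = "panel D: dimerization of FGF2 signaling trimers"))
  # cHSPG release from (undimerized) trimers populates the FGF2:FGFR1 pool
  add(rule("TRIrelH", "unbinding",
           list(pattern(c("FGFR1", "FGF2", "cHSPG"),
                        cond = list(c(d = "free"), NULL, NULL),
                        bonds = list(c(1, "l", 2, "r"), c(2, "h", 3, "hs")),
                        comp = "surface")),
           rate_fwd = "koff_trimer_h", delbond = 2L,
           notes = "panel D: cHSPG dissociation from the trimer"))

  ## --- PF4 axis (panel E) ----------------------------------------------------
  add(bind_rule("P.CXCR3", P1("PF4", hs = "free", f = "free", comp = "interstitium"), "r",
                P1("CXCR3", comp = "surface"), "l",
                "kon_p_cxcr3", "koff_p_cxcr3", "panel E: PF4+CXCR3"))
  add(bind_rule("P.LRP1", P1("PF4", hs = "free", f = "free", comp = "interstitium"), "r",
                P1("LRP1", comp = "surface"), "l",
                "kon_p_lrp1", "koff_p_lrp1", "panel E: PF4+LRP1 (competes with TSP1)"))
  add(bind_rule("P.cH", P1("PF4", r = "free", f = "free", comp = "interstitium"), "hs",
                P1("cHSPG", comp = "surface"), "hs",
                "kon_p_ch", "koff_p_ch", "panel E: PF4+cHSPG"))
  add(bind_rule("M9.LRP1", P1("MMP9", comp = "interstitium"), "r",
                P1("LRP1", comp = "surface"), "l",
                "kon_m9_lrp1", "koff_m9_lrp1", "panel E: MMP9+LRP1"))

  ## --- interstitial interactions (panel F) -----------------------------------
  add(bind_rule("T.V165", P1("TSP1", hs = "free", r = "free", comp = "interstitium"), "f",
                P1("V165", n = "free", comp = "interstitium"), "r",
                "kon_t_v", "koff_t_v", "panel F: TSP1.V165"))
  add(bind_rule("T.V121", P1("TSP1", hs = "free", r = "free", comp = "interstitium"), "f",
                P1("V121", comp = "interstitium"), "r",
                "kon_t_v", "koff_t_v", "panel F: TSP1.V121"))
  add(bind_rule("T.F", P1("TSP1", hs = "free", r = "free", comp = "interstitium"), "f",
                P1("FGF2", h = "free", comp = "interstitium"), "r",
                "kon_t_f", "koff_t_f", "panel F: TSP1.FGF2"))
  add(bind_rule("P.V165", P1("PF4", hs = "free", r = "free", comp = "interstitium"), "f",
                P1("V165", r = "free", comp = "interstitium"), "n",
                "kon_p_v", "koff_p_v", "panel F: PF4.V165"))
  add(bind_rule("P.F", P1("PF4", hs = "free", r = "free", comp = "interstitium"), "f",
                P1("FGF2", r = "free", comp = "interstitium"), "h",
                "kon_p_f", "koff_p_f", "panel F: PF4.FGF2"))
  add(bind_rule("V.iH", P1("V165", r = "free", comp = "interstitium"), "n",
                P1("iHSPG", comp = "interstitium"), "hs",
                "kon_v_ih", "koff_v_ih", "panel F: V165+iHSPG"))
  add(bind_rule("F.iH", P1("FGF2", r = "free", comp = "interstitium"), "h",
                P1("iHSPG", comp = "interstitium"), "hs",
                "kon_f_ih", "koff_f_ih", "panel F: FGF2+iHSPG"))
  add(bind_rule("T.iH", P1("TSP1", r = "free", f = "free", comp = "interstitium"), "hs",
                P1("iHSPG", comp = "interstitium"), "hs",
                "kon_t_ih", "koff_t_ih", "panel F: TSP1+iHSPG"))
  add(bind_rule("P.iH", P1("PF4", r = "free", f = "free", comp = "interstitium"), "hs",
                P1("iHSPG", comp = "interstitium"), "hs",
                "kon_p_ih", "koff_p_ih", "panel F: PF4+iHSPG"))
  # proteolysis chain
  add(rule("M3actM9", "catalytic_conversion",
           list(pattern("MMP3", comp = "interstitium"),
                pattern("proMMP9", comp = "interstitium")),
           rate_fwd = "k_act_m9",
           products = list(complex_new("MMP3", list(), "interstitium", M),
                           complex_new("MMP9", list(), "interstitium", M)),
           conversion = c(proMMP9 = "MMP9"),
           notes = "panel F: MMP3 activates proMMP9"))
  add(rule("M9clT", "catalytic_conversion",
           list(pattern("MMP9", cond = list(c(r = "free")), comp = "interstitium"),
                pattern("TSP1", cond = list(c(hs = "free", r = "free", f = "free")),
                        comp = "interstitium")),
           rate_fwd = "k_cl_t",
           products = list(complex_new("MMP9", list(), "interstitium", M),
                           complex_new("TSP1c", list(), "interstitium", M)),
           conversion = c(TSP1 = "TSP1c"),
           notes = "panel F: MMP9 cleaves TSP1 to inactive TSP1c"))
  add(rule("M9clV", "catalytic_conversion",
           list(pattern("MMP9", cond = list(c(r = "free")), comp = "interstitium"),
                pattern("V165", cond = list(c(r = "free", n = "free")),
                        comp = "interstitium")),
           rate_fwd = "k_cl_v",
           products = list(complex_new("MMP9", list(), "interstitium", M),
                           complex_new("V114", list(), "interstitium", M)),
           conversion = c(V165 = "V114"),
           notes = "panel F: MMP-mediated cleavage of V165 to inactive V114"))

  ## --- production ------------------------------------------------------------
  for (ft in c("V165", "V121", "FGF2", "TSP1", "MMP3", "proMMP9")) {
    for (side in c("ec", "tc")) {
      add(prod_rule(paste0("q.", ft, ".", side), ft,
                    paste0("q_", tolower(ft), "_", side), M,
                    paste0("secretion of ", ft, " by ",
                           if (side == "ec") "endothelial" else "tumor", " cells")))
    }
  }
  add(prod_rule("q.PF4", "PF4", "q_pf4", M,
                "generic tissue-level PF4 source (platelet release)"))

  ## --- degradation of free soluble species -----------------------------------
  for (ft in c("V165", "V121", "V114", "FGF2", "TSP1", "TSP1c", "PF4",
               "MMP3", "proMMP9", "MMP9")) {
    add(deg_rule(paste0("deg.", ft), ft, paste0("kdeg_", tolower(ft)), M))
  }

  ## --- internalization (ligand destroyed, receptors/cHSPG recycled) ----------
  add(int_rule("int.R1", "VEGFR1", "l", "bound"))
  add(int_rule("int.R2", "VEGFR2", "l", "bound"))
  add(int_rule("int.N", "NRP1", "v", "bound"))
  add(int_rule("int.FGFR1", "FGFR1", "l", "bound"))
  add(int_rule("int.CD36", "CD36", "l", "bound"))
  add(int_rule("int.CD47", "CD47", "l", "bound"))
  add(int_rule("int.LRP1", "LRP1", "l", "bound"))
  add(int_rule("int.B1", "B1", "l", "bound"))
  add(int_rule("int.CXCR3", "CXCR3", "l", "bound"))
  add(int_rule("int.cH.V", "cHSPG", "hs", "V165:n"))
  add(int_rule("int.cH.F", "cHSPG", "hs", "FGF2:h"))
  add(int_rule("int.cH.T", "cHSPG", "hs", "TSP1:hs"))
  add(int_rule("int.cH.P", "cHSPG", "hs", "PF4:hs"))

  spec <- model_spec(M, builtin_seeds(M), r, name = "angionet")
  if (validate) assert_valid_spec(spec)
  spec
}

#' Rule-to-schematic mapping of the builtin catalogue
#'
#' @return Tibble with `rule_id`, `class`, `rate_fwd`, `rate_rev`, `notes`
#'   (the schematic panel each rule was transcribed from).
#' @export
builtin_rule_map <- function() {
  spec <- builtin_model(validate = FALSE)
  bind_rows(lapply(spec$rules, function(r) {
    tibble(rule_id = r$id, class = r$class, rate_fwd = r$rate_fwd,
           rate_rev = r$rate_rev, notes = r$notes)
  }))
}

# ---- toy fixtures -----------------------------------------------------------

#' Minimal ligand-receptor toy model
#'
#' One soluble ligand L, one surface receptor R, one reversible binding rule;
#' used throughout the tests as a hand-enumerable fixture (3 species, 2
#' directed reactions).
#'
#' @param kon_name,koff_name Rate-constant names to reference.
#' @return An `angio_model`.
#' @export
toy_model <- function(kon_name = "kon_lr", koff_name = "koff_lr") {
  M <- list(monomer("L", "b", "soluble"),
            monomer("R", "b", "surface_fixed"))
  names(M) <- c("L", "R")
  seeds <- list(
    c(free_species("L", "interstitium", M), list(init = "zero")),
    c(free_species("R", "endothelial_surface", M), list(init = "density:R:ec"))
  )
  rules <- list(
    bind_rule("L.R", P1("L", comp = "interstitium"), "b",
              P1("R", comp = "surface"), "b", kon_name, koff_name,
              "toy reversible binding")
  )
  model_spec(M, seeds, rules, name = "toy_lr")
}
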