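test_that("each mechanism assembles the species and reactions it claims", {
  m_int <- build_model("INTEGRATED")
  expect_true(all(c("pS24nTIF1g", "pS2nTIF1g", "S4ubn", "S4ubc", "FAM") %in%
                    model_species(m_int)$name))
  rx <- model_reactions(m_int)
  expect_true("dub_S4ub" %in% rx$id)            # FAM-dependent deubiquitination
  expect_true("ubiq_tern" %in% rx$id)           # ternary-complex dissolution
  # pS2nTIF1g is only produced by ternary dissolution, never by association
  expect_false(any(grepl("pS2nTIF1g", rx$reactants) & grepl("TIF1g_n", rx$reactants)))

  m_rep <- build_model("REPRESSOR")
  expect_false(any(c("pS2nTIF1g", "pS24nTIF1g") %in% model_species(m_rep)$name))
  expect_true(all(c("S4ubn", "FAM") %in% model_species(m_rep)$name))

  m_cmp <- build_model("COMPETITION")
  expect_false(any(c("S4ubn", "S4ubc", "FAM") %in% model_species(m_cmp)$name))
  expect_true(all(c("pS2nTIF1g", "S4nTIF1g") %in% model_species(m_cmp)$name))

  expect_error(build_model("NONSENSE"))
  expect_error(build_model("INTEGRATED", init = c(TIF1g_n = -5)), "negative")
  expect_error(build_model("INTEGRATED", init = c(NotASpecies = 1)), "unknown species")
  expect_error(model_variant("COMPETITION", fam_included = TRUE), "FAM")
})

test_that("conservation weight vectors lie in the left null space", {
  for (mech in c("BASE", "REPRESSOR", "COMPETITION", "INTEGRATED")) {
    sys <- build_model(mech)
    S <- sys$smat
    for (g in names(sys$conservation)) {
      w <- stats::setNames(numeric(nrow(S)), rownames(S))
      w[names(sys$conservation[[g]])] <- sys$conservation[[g]]
      expect_lt(max(abs(w %*% S)), 1e-12)
    }
    # Smads, TIF1g, FAM, PPase are conserved; receptors are exempt
    expect_true(all(c("Smad2", "Smad4", "PPase") %in% names(sys$conservation)))
  }
})

test_that("the zero state only carries constitutive receptor synthesis", {
  sys <- build_model("INTEGRATED")
  dy <- model_rhs(sys, rep(0, nrow(model_species(sys))), 0, ligand = 0)
  p <- default_parameters()
  expect_equal(unname(dy[["RI"]]), unname(p[["p_RI"]]))
  expect_equal(unname(dy[["RII"]]), unname(p[["p_RII"]]))
  expect_true(all(dy[setdiff(names(dy), c("RI", "RII"))] == 0))
})

test_that("bimolecular fluxes scale with the product of reactant concentrations", {
  sys <- build_model("INTEGRATED")
  st <- stats::setNames(model_species(sys)$initial, model_species(sys)$name)
  st["pS2n"] <- 5; st["S4n"] <- 8
  f1 <- reaction_fluxes(sys, st)[["hetero_n_on"]]
  st2 <- st; st2["pS2n"] <- 10; st2["S4n"] <- 16
  f2 <- reaction_fluxes(sys, st2)[["hetero_n_on"]]
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
  # second-order homomeric association quadruples too
  st["pS2c"] <- 3; st2 <- st; st2["pS2c"] <- 6
  expect_equal(reaction_fluxes(sys, st2)[["homo_c_on"]],
               4 * reaction_fluxes(sys, st)[["homo_c_on"]], tolerance = 1e-12)
})

test_that("without TIF1g every TIF1g-containing flux is identically zero", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 0))
  st <- stats::setNames(model_species(sys)$initial, model_species(sys)$name)
  st[c("pS24n", "pS2n", "S4n")] <- c(10, 4, 20) # active signaling, no TIF1g
  fl <- reaction_fluxes(sys, st, ligand = 10)
  tif_rx <- c("tern_on", "tern_off", "ubiq_tern", "pS2T_off", "exp_S4ub", "dub_S4ub")
  expect_true(all(fl[tif_rx] == 0))
  expect_gt(fl[["hetero_n_on"]], 0)
})

test_that("conserved totals count every complex once per constituent", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 25))
  st <- stats::setNames(model_species(sys)$initial, model_species(sys)$name)
  tot <- conserved_totals(sys, st)
  expect_equal(unname(tot[["Smad4"]]), 50)      # the default initialization
  expect_equal(unname(tot[["Smad2"]]), 60.6)
  # moving Smad4 into the ubiquitinated pool leaves the total unchanged
  st2 <- st; st2["S4c"] <- 0; st2["S4ubc"] <- st[["S4c"]]
  expect_equal(unname(conserved_totals(sys, st2)[["Smad4"]]), 50)
  # a nuclear ternary complex counts for Smad2, Smad4 and TIF1g at once
  st3 <- st; st3["pS24nTIF1g"] <- 2
  tot3 <- conserved_totals(sys, st3)
  vn_over_vc <- 1.0e-12 / 2.27e-12
  expect_equal(unname(tot3[["Smad4"]] - tot[["Smad4"]]), 2 * vn_over_vc,
               tolerance = 1e-12)
  expect_equal(unname(tot3[["TIF1g"]] - tot[["TIF1g"]]), 2 * vn_over_vc,
               tolerance = 1e-12)
})

test_that("state validation rejects dimension mismatch and non-finite entries", {
  sys <- build_model("BASE")
  expect_error(model_rhs(sys, c(1, 2, 3)), "species count")
  st <- model_species(sys)$initial
  st[1] <- NaN
  expect_error(model_rhs(sys, st), "NaN/Inf")
  st[1] <- -1 # far beyond the undershoot tolerance
  expect_error(model_rhs(sys, st), "negative")
})
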