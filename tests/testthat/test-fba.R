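# The miniature network's optimum at MG1655-like bounds was verified against
# an independent LP solver (scipy HiGHS): mu = 1.0907216, acetate efflux
# 1.1428 at glc 9.5, o2 13.9, gam 60.25. Frozen here.
test_that("FBA on the miniature network reproduces the verified optimum", {
  mod <- mini_ecoli_model(gam = 60.25, v_glc_max = 9.5, v_o2_max = 13.9,
                          yield_glc = 5)
  sol <- fba_solve(mod)
  expect_equal(sol$status, "optimal")
  # tolerance covers the solver's degenerate-vertex fallback (~1e-8 bound jitter)
  expect_equal(sol$objective, 1.090721649484536, tolerance = 1e-7)
  expect_equal(unname(sol$fluxes["EX_ac"]), 1.142784, tolerance = 1e-5)
  expect_equal(unname(sol$fluxes["EX_glc"]), -9.5, tolerance = 1e-7)
  # steady state holds
  expect_lt(max(abs(mod$S %*% sol$fluxes)), 1e-8)
})

test_that("anaerobic FBA ferments: all carbon to acetate, no respiration", {
  mod <- mini_ecoli_model(gam = 60, v_glc_max = 10, v_o2_max = 0)
  sol <- fba_solve(mod)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$fluxes["OX"]), 0, tolerance = 1e-6)
  expect_gt(unname(sol$fluxes["EX_ac"]), 0)
  expect_lt(sol$objective, fba_solve(mini_ecoli_model(gam = 60))$objective)
})

test_that("fitting recovers known parameters from a self-generated record", {
  mod <- mini_ecoli_model()
  # an oxygen-limited truth so aerobic acetate overflow is nonzero — with
  # zero overflow the (v_o2_max, GAM) pair is not identifiable from growth
  # alone (a ridge of equivalent fits)
  truth <- list(v_o2 = 6, gam_a = 40, gam_n = 45)
  rec <- predict_strain_record(mod, "toy", v_glc_aero = 8, v_glc_anaero = 12,
                               v_o2_max = truth$v_o2, gam_aero = truth$gam_a,
                               gam_anaero = truth$gam_n)
  expect_gt(rec$v_ac_aero, 0)
  fit <- fit_strain_parameters(mod, rec)
  expect_lt(abs(fit$v_o2_max - truth$v_o2), 0.5)
  expect_lt(abs(fit$gam_aero - truth$gam_a), 2)
  expect_lt(abs(fit$gam_anaero - truth$gam_n), 2)
  # the zero-residual case: a model matching the record exactly fits with ~0 error
  expect_true(all(fit$residual_errors$error_pct < 1))
})

test_that("fitting reports infeasibility and missing exchanges clearly", {
  mod <- mini_ecoli_model()
  expect_error(
    fba_model(mod$S, mod$lb, mod$ub, "BIOMASS",
              exchanges = list(glucose = "EX_nope", oxygen = "EX_o2",
                               acetate = "EX_ac")),
    "not in model")
  # forced glucose uptake with every consuming pathway shut: no steady state
  bad <- set_bound(mod, "EX_glc", ub = -5)
  bad <- set_bound(bad, "FERM", ub = 0)
  bad <- set_bound(bad, "OX", ub = 0)
  bad <- set_bound(bad, "BIOMASS", ub = 0)
  expect_equal(fba_solve(bad)$status, "infeasible")
  rec <- strain_record("MG1655")
  expect_error(fit_strain_parameters(bad, rec), "infeasible")
})

test_that("LP flux tables have the contract shape and dormancy at zero carbon", {
  mod <- mini_ecoli_model(gam = 55, v_glc_max = 9.5, v_o2_max = 12)
  params <- list(v_o2_max = 12, gam_aero = 55)
  ft <- build_flux_table(mod, "GLUCOSE_UTILIZER", params,
                         n_carbon = 8, n_o2 = 10)
  expect_equal(dim(ft$grids$v_bm), c(8, 10))
  expect_true(all(ft$grids$v_bm[1, ] == 0))
  expect_true(all(ft$grids$v_bm >= 0))
  # default axis divisions are the standard 50 x 160
  expect_equal(formals(build_flux_table)$n_carbon, 50)
  expect_equal(formals(build_flux_table)$n_o2, 160)
})

test_that("LP-table growth is monotone and matches independent re-solves", {
  mod <- mini_ecoli_model(gam = 55, v_glc_max = 9.5, v_o2_max = 12)
  params <- list(v_o2_max = 12, gam_aero = 55)
  ft <- build_flux_table(mod, "GLUCOSE_UTILIZER", params,
                         n_carbon = 6, n_o2 = 6)
  # monotone non-decreasing along both axes (LP relaxation argument)
  expect_true(all(diff(ft$grids$v_bm) >= -1e-8))
  expect_true(all(t(diff(t(ft$grids$v_bm))) >= -1e-8))
  # brute-force re-solve of every node with the independent oracle
  for (i in seq_along(ft$carbon_axis)) {
    for (j in seq_along(ft$o2_axis)) {
      m <- set_bound(mod, "EX_glc", lb = -ft$carbon_axis[i])
      m <- set_bound(m, "EX_o2", lb = -ft$o2_axis[j])
      m <- set_gam(m, 55)
      oracle <- scipy_fba(m)
      expect_equal(ft$grids$v_bm[i, j],
                   if (is.null(oracle$obj)) 0 else max(oracle$obj, 0),
                   tolerance = 1e-6,
                   info = paste("node", i, j))
    }
  }
})

test_that("acetate-phenotype LP tables grow on acetate only with oxygen", {
  mod <- mini_ecoli_model(gam = 55)
  ft <- build_flux_table(mod, "ACETATE_UTILIZER",
                         list(v_o2_max = 12, gam_aero = 55),
                         n_carbon = 6, n_o2 = 6, ac_uptake_max = 10)
  expect_equal(max(ft$carbon_axis), 10)
  expect_true(all(ft$grids$v_bm[, 1] == 0))   # anoxic: no acetate growth
  expect_gt(ft$grids$v_bm[6, 6], 0)
  expect_true(all(ft$grids$v_glc == 0))       # glucose shut off
})

test_that("SBML round trip preserves the model and its optimum", {
  mod <- mini_ecoli_model(gam = 60.25, v_glc_max = 9.5, v_o2_max = 13.9,
                          yield_glc = 5)
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(mod, p)
  back <- read_sbml_model(p, exchanges = mod$exchanges, atp_met = "atp")
  expect_equal(sort(colnames(back$S)), sort(colnames(mod$S)))
  expect_equal(back$S[rownames(mod$S), colnames(mod$S)], mod$S)
  expect_equal(back$lb, mod$lb)
  expect_equal(back$objective, "BIOMASS")
  expect_equal(fba_solve(back)$objective, fba_solve(mod)$objective,
               tolerance = 1e-7)
})

test_that("BiGG-dialect JSON models are read correctly", {
  mod <- mini_ecoli_model(gam = 50, v_glc_max = 8, v_o2_max = 10)
  p <- withr::local_tempfile(fileext = ".json")
  bigg <- list(
    id = "toy_bigg",
    metabolites = lapply(rownames(mod$S), function(m) list(id = m)),
    reactions = lapply(seq_len(ncol(mod$S)), function(k) {
      col <- mod$S[, k]
      list(id = colnames(mod$S)[k],
           metabolites = as.list(col[col != 0]),
           lower_bound = mod$lb[k],
           upper_bound = min(mod$ub[k], 1000),
           objective_coefficient = as.numeric(colnames(mod$S)[k] == "BIOMASS"))
    })
  )
  jsonlite::write_json(bigg, p, auto_unbox = TRUE, digits = NA)
  back <- read_bigg_json(p, exchanges = mod$exchanges, atp_met = "atp")
  expect_equal(back$S[rownames(mod$S), colnames(mod$S)], mod$S)
  expect_equal(fba_solve(back)$objective, fba_solve(mod)$objective,
               tolerance = 1e-7)
})
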